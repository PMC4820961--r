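#' Pipeline configuration
#'
#' A single object driving [run_pipeline()]: either a simulation block (a
#' [sim_config()]) or paths to existing TSV inputs, stage toggles and the
#' thresholds of each stage.
#'
#' @param sim A [sim_config()] to generate the inputs, or `NULL` to read
#'   them from `paths`.
#' @param paths Named list of input TSV paths (`pedigree`, `genotypes`,
#'   `snp_info`, `methylation_m`, `covariates`) when `sim` is `NULL`.
#' @param out_dir Output directory.
#' @param seed Integer seed; fans out to per-stage child seeds.
#' @param grm_cutoff Threshold for [threshold_grm()].
#' @param maf_min MAF filter for [compute_grm()].
#' @param alpha Family-wise error rate for significance flags.
#' @param run_twin,run_two_grm,run_moderation,run_annotation Stage toggles.
#' @param moderation_grm Genetic kernel for the moderation models:
#'   `"pedigree"` (expected IBD relatedness from the pedigree; exact and
#'   block-diagonal, the right choice when the SNP panel is small) or
#'   `"ibd"` (the thresholded SNP-based GRM, appropriate with dense
#'   genotyping).
#' @param genes,cgis Optional annotation tibbles (see
#'   [assign_gene_region()], [assign_cgi_region()]); required when
#'   `run_annotation` is `TRUE`.
#' @param sites Tibble with `site_id`, `chrom`, `pos` for annotation; when
#'   `NULL`, synthetic positions are generated for simulated data.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = desk_config(seed = seed), paths = NULL,
                       out_dir = tempfile("methvc_run_"), seed = 1,
                       grm_cutoff = 0.05, maf_min = 0.01, alpha = 0.05,
                       run_twin = TRUE, run_two_grm = TRUE,
                       run_moderation = TRUE, run_annotation = FALSE,
                       moderation_grm = c("pedigree", "ibd"),
                       genes = NULL, cgis = NULL, sites = NULL) {
  moderation_grm <- match.arg(moderation_grm)
  assert_that(alpha > 0 && alpha < 1, "`alpha` must be in (0, 1)")
  if (is.null(sim)) {
    assert_that(!is.null(paths), "either `sim` or `paths` must be given")
    for (p in unlist(paths)) {
      assert_that(file.exists(p), paste0("input file not found: ", p))
    }
  }
  if (run_annotation) {
    assert_that(!is.null(genes) && !is.null(cgis),
                "annotation stage needs `genes` and `cgis` tables")
  }
  structure(list(sim = sim, paths = paths, out_dir = out_dir, seed = seed,
                 grm_cutoff = grm_cutoff, maf_min = maf_min, alpha = alpha,
                 run_twin = run_twin, run_two_grm = run_two_grm,
                 run_moderation = run_moderation,
                 run_annotation = run_annotation,
                 moderation_grm = moderation_grm,
                 genes = genes, cgis = cgis, sites = sites),
            class = "run_config")
}

#' Run the full variance-decomposition pipeline
#'
#' Stage order mirrors the analysis sequence: data generation (or loading),
#' imputation of missing cells, covariate residualization (with genotype
#' PCs for GRM-based stages, without them for twin stages),
#' z-standardization, twin correlations and models, GRM construction and
#' the two-GRM model, age and sex moderation models, optional annotation
#' and enrichment, and catalogue assembly. Every stage records its
#' parameters in a JSON provenance file; per-site failures are isolated in
#' `status` columns rather than aborting the run.
#'
#' @param config A [run_config()].
#' @return List with `catalogue` (tibble), component results, and
#'   `provenance` (also written to `out_dir/provenance.json`). The
#'   catalogue is written to `out_dir/catalogue.tsv`.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "`config` must be a run_config")
  # optimizer restarts draw from the RNG; seed the whole run so identical
  # configs give identical catalogues regardless of ambient RNG state
  with_seed(child_seed(config$seed, 1), run_pipeline_impl(config))
}

run_pipeline_impl <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(package_version = as.character(utils::packageVersion("methvc")),
               seed = config$seed, stages = list())
  stamp <- function(stage, ...) {
    prov$stages[[stage]] <<- list(...)
  }

  # -- inputs ---------------------------------------------------------------
  if (!is.null(config$sim)) {
    ds <- generate_dataset(config$sim, file.path(config$out_dir, "data"))
    ped <- ds$pedigree; covars <- ds$covariates; geno <- ds$genotypes
    meth_m <- ds$methylation_m; beta <- ds$methylation_beta
    truth <- ds$truth
    stamp("simulate", n_samples = nrow(ped), n_sites = nrow(meth_m),
          n_snps = ncol(geno$dosage), seed = config$sim$seed)
  } else {
    ped <- readr::read_tsv(config$paths$pedigree, show_col_types = FALSE)
    covars <- readr::read_tsv(config$paths$covariates, show_col_types = FALSE)
    geno_df <- readr::read_tsv(config$paths$genotypes, show_col_types = FALSE)
    dosage <- as.matrix(geno_df[, -1]); rownames(dosage) <- geno_df[[1]]
    geno <- list(dosage = dosage,
                 snp_info = readr::read_tsv(config$paths$snp_info,
                                            show_col_types = FALSE))
    meth_m <- read_meth_matrix(config$paths$methylation_m)
    beta <- NULL; truth <- NULL
    stamp("load", paths = config$paths)
  }
  if (!is.null(covars$array_row)) covars$array_row <- factor(covars$array_row)
  if (!is.null(covars$plate)) covars$plate <- factor(covars$plate)

  # -- imputation -----------------------------------------------------------
  imp <- impute_missing(meth_m, method = "site_mean")
  meth_m <- imp$meth
  stamp("impute", method = "site_mean", n_imputed = sum(imp$imputed))

  descr <- tibble(site_id = rownames(meth_m),
                  mean_m = rowMeans(meth_m),
                  sd_m = apply(meth_m, 1, sd))
  if (!is.null(beta)) {
    descr$mean_beta <- rowMeans(beta, na.rm = TRUE)
    descr$sd_beta <- apply(beta, 1, sd, na.rm = TRUE)
  }

  # -- GRMs and residualization --------------------------------------------
  A_ibs <- compute_grm(geno, maf_min = config$maf_min)
  A_ibd <- threshold_grm(A_ibs, cutoff = config$grm_cutoff)
  pcs <- genotype_pcs(A_ibs, k = 10)
  stamp("grm", n_snps = A_ibs$n_snps, cutoff = config$grm_cutoff)

  design_nopc <- build_covariate_design(covars)
  design_pc <- build_covariate_design(covars, genotype_pcs = pcs)
  res_twin <- residualize(meth_m, design_nopc)
  res_grm <- residualize(meth_m, design_pc)
  z_twin <- zstandardize(res_twin$meth)
  z_grm <- zstandardize(res_grm$meth)
  stamp("residualize", mean_r2_no_pcs = res_twin$mean_r2,
        mean_r2_with_pcs = res_grm$mean_r2)

  parts <- list(descr)

  # -- twin stage -----------------------------------------------------------
  if (config$run_twin) {
    twin_tbl <- fit_twin_models_sites(z_twin, ped)
    n_ok <- sum(twin_tbl$status == "ok")
    alpha_twin <- multiple_testing_threshold(config$alpha, max(n_ok, 1))
    twin_tbl$sig_a <- twin_tbl$p_a < alpha_twin
    parts <- c(parts, list(twin_tbl))
    stamp("twin", n_sites_ok = n_ok, alpha = alpha_twin)
  }

  # -- two-GRM stage --------------------------------------------------------
  if (config$run_two_grm) {
    vc_tbl <- fit_two_grm_sites(z_grm, A_ibs, A_ibd)
    parts <- c(parts, list(vc_tbl))
    stamp("two_grm", n_sites_ok = sum(vc_tbl$status == "ok"))
  }

  # -- moderation stage -----------------------------------------------------
  if (config$run_moderation) {
    m_age <- moderator_from_age(covars$age)
    m_sex <- moderator_from_sex(covars$sex)
    A_mod <- if (config$moderation_grm == "pedigree") {
      pedigree_kinship(ped)
    } else A_ibd
    age_tbl <- fit_moderation_sites(z_grm, A_mod, m_age)
    sex_tbl <- fit_moderation_sites(z_grm, A_mod, m_sex)
    names(age_tbl)[-1] <- paste0("age_", names(age_tbl)[-1])
    names(sex_tbl)[-1] <- paste0("sex_", names(sex_tbl)[-1])
    n_ok <- sum(age_tbl$age_status == "ok") + sum(sex_tbl$sex_status == "ok")
    alpha_int <- multiple_testing_threshold(config$alpha,
                                            max(nrow(age_tbl) + nrow(sex_tbl), 1))
    age_tbl$sig_age_g <- age_tbl$age_p_g < alpha_int
    age_tbl$sig_age_e <- age_tbl$age_p_e < alpha_int
    sex_tbl$sig_sex_g <- sex_tbl$sex_p_g < alpha_int
    sex_tbl$sig_sex_e <- sex_tbl$sex_p_e < alpha_int
    parts <- c(parts, list(age_tbl, sex_tbl))
    stamp("moderation", alpha = alpha_int, n_fits_ok = n_ok)
  }

  catalogue <- Reduce(function(a, b) dplyr::left_join(a, b, by = "site_id"),
                      parts)

  # -- categories -----------------------------------------------------------
  if (config$run_two_grm) {
    cats <- categorize_sites(catalogue,
                             sd_beta = if (!is.null(beta))
                               setNames(descr$sd_beta, descr$site_id))
    catalogue <- dplyr::left_join(catalogue, cats, by = "site_id")
  }

  # -- annotation -----------------------------------------------------------
  enrichment <- NULL
  if (config$run_annotation) {
    sites <- config$sites
    assert_that(!is.null(sites), "annotation needs a `sites` position table")
    sites <- sites[match(catalogue$site_id, sites$site_id), ]
    ann <- tibble(site_id = catalogue$site_id,
                  gene_region = assign_gene_region(sites, config$genes),
                  cgi_region = assign_cgi_region(sites, config$cgis))
    catalogue <- dplyr::left_join(catalogue, ann, by = "site_id")
    if (config$run_two_grm && any(catalogue$high_h2, na.rm = TRUE)) {
      enrichment <- enrichment_test(
        catalogue$site_id[catalogue$high_h2 %in% TRUE],
        catalogue$site_id,
        setNames(ann$gene_region, ann$site_id))
    }
    stamp("annotation", n_genes = nrow(config$genes), n_cgis = nrow(config$cgis))
  }

  write_catalogue(catalogue, file.path(config$out_dir, "catalogue.tsv"))
  prov$config <- list(seed = config$seed, grm_cutoff = config$grm_cutoff,
                      maf_min = config$maf_min, alpha = config$alpha,
                      stages = list(twin = config$run_twin,
                                    two_grm = config$run_two_grm,
                                    moderation = config$run_moderation,
                                    annotation = config$run_annotation))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  list(catalogue = catalogue, truth = truth, enrichment = enrichment,
       grm_ibs = A_ibs, grm_ibd = A_ibd, pedigree = ped,
       provenance = prov, out_dir = config$out_dir)
}
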