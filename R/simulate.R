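#' Simulation configuration for a twin-family methylome
#'
#' Bundles every knob of the synthetic data generator. The defaults emulate
#' the study population the estimators are aimed at: an adult twin cohort
#' with mean age 37.2 (s.d. 13.3) years, ages spanning 17-79, and about
#' two-thirds female participants. The `desk` preset (see [desk_config()])
#' scales the cohort down so that a full pipeline run takes minutes.
#'
#' @param n_mz_pairs,n_dz_pairs Number of monozygotic / dizygotic twin pairs.
#' @param n_parents Number of parent individuals to include in the sample
#'   (assigned two per family, starting from the first MZ family).
#' @param n_snps Number of biallelic SNPs to simulate.
#' @param maf_range Interval the minor-allele frequencies are drawn from.
#' @param site_params Data frame of per-site generative parameters, one row
#'   per methylation site; see [site_params()].
#' @param age_mean,age_sd,age_range Twin age distribution (years); draws are
#'   truncated to `age_range`.
#' @param prop_female Probability that a twin individual is female.
#' @param missing_rate Per-cell probability of missing methylation values
#'   injected by [generate_dataset()].
#' @param seed Integer seed; fully determines all generated data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 200, n_dz_pairs = 200, n_parents = 0,
                       n_snps = 500, maf_range = c(0.01, 0.5),
                       site_params = sample_site_params(50, seed = 1),
                       age_mean = 37.2, age_sd = 13.3, age_range = c(17, 79),
                       prop_female = 0.66, missing_rate = 0.001, seed = NULL) {
  assert_that(n_mz_pairs >= 0 && n_dz_pairs >= 0 && n_parents >= 0,
              "counts must be non-negative")
  assert_that(n_mz_pairs + n_dz_pairs >= 1, "at least one twin family is required")
  assert_that(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
              "`maf_range` must lie within (0, 0.5]")
  assert_that(age_range[1] < age_range[2], "`age_range` must be increasing")
  assert_that(prop_female >= 0 && prop_female <= 1, "`prop_female` must be in [0, 1]")
  assert_that(missing_rate >= 0 && missing_rate < 1, "`missing_rate` must be in [0, 1)")
  structure(list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
                 n_parents = n_parents, n_snps = n_snps, maf_range = maf_range,
                 site_params = site_params, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, prop_female = prop_female,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_config")
}

#' @rdname sim_config
#' @param n_sites Number of methylation sites in the desk preset.
#' @export
desk_config <- function(seed = NULL, n_sites = 50) {
  sim_config(n_mz_pairs = 200, n_dz_pairs = 200, n_snps = 500,
             site_params = sample_site_params(n_sites, seed = seed %||% 1),
             seed = seed)
}

#' Per-site generative parameters
#'
#' One methylation site is generated as the sum of a SNP-tagged additive
#' genetic score, an untagged polygenic additive deviate, a common (family)
#' environmental deviate, a dominance deviate, and a unique environmental
#' deviate. The five variance fractions must sum to one at moderator value
#' zero. Moderation slopes act multiplicatively on the polygenic and unique
#' environmental standard deviations: `s(m) = sigma + beta * m` with `m`
#' the z-scored age or 0/1 sex indicator.
#'
#' @param var_snp,var_ped,var_c,var_d,var_e Variance fractions (SNP-tagged
#'   additive, untagged additive, common environment, dominance, unique
#'   environment); must be non-negative and sum to 1.
#' @param n_causal Number of causal SNPs behind `var_snp`.
#' @param beta_g_age,beta_e_age,beta_g_sex,beta_e_sex Moderation slopes on
#'   the genetic / environmental standard deviation per unit moderator.
#' @param baseline_beta Mean methylation proportion of the site, in (0, 1).
#' @param site_id Optional site identifier.
#' @return A one-row tibble.
#' @export
site_params <- function(var_snp = 0, var_ped = 0.2, var_c = 0, var_d = 0,
                        var_e = 0.8, n_causal = 5,
                        beta_g_age = 0, beta_e_age = 0,
                        beta_g_sex = 0, beta_e_sex = 0,
                        baseline_beta = 0.5, site_id = NULL) {
  fr <- c(var_snp, var_ped, var_c, var_d, var_e)
  assert_that(all(fr >= 0), "variance fractions must be non-negative")
  assert_that(abs(sum(fr) - 1) < 1e-8,
              "variance fractions must sum to 1 at moderator value 0")
  assert_that(baseline_beta > 0 && baseline_beta < 1,
              "`baseline_beta` must lie in (0, 1)")
  tibble(site_id = site_id %||% NA_character_,
         var_snp = var_snp, var_ped = var_ped, var_c = var_c,
         var_d = var_d, var_e = var_e, n_causal = n_causal,
         beta_g_age = beta_g_age, beta_e_age = beta_e_age,
         beta_g_sex = beta_g_sex, beta_e_sex = beta_e_sex,
         baseline_beta = baseline_beta)
}

#' Draw a spread of per-site truths for recovery experiments
#'
#' Produces sites whose SNP-tagged, untagged-additive and environmental
#' fractions vary across the realistic range (heritabilities roughly 0 to
#' 0.7, SNP-tagged share of the genetic variance 0 to 1), with no
#' moderation; moderated sites are added explicitly by the caller.
#'
#' @param n_sites Number of sites.
#' @param seed Integer seed.
#' @return Tibble with `n_sites` rows of [site_params()] values.
#' @export
sample_site_params <- function(n_sites, seed = NULL) {
  with_seed(seed, {
    h2 <- runif(n_sites, 0.05, 0.7)
    snp_share <- runif(n_sites, 0, 1)
    var_snp <- h2 * snp_share
    var_ped <- h2 * (1 - snp_share)
    purrr::pmap_dfr(list(var_snp, var_ped, seq_len(n_sites)),
      function(vs, vp, i) {
        site_params(var_snp = vs, var_ped = vp, var_e = 1 - vs - vp,
                    baseline_beta = runif(1, 0.1, 0.9),
                    site_id = sprintf("cg%06d", i))
      })
  })
}

#' Simulate a twin-family pedigree
#'
#' Builds families of MZ and DZ twin pairs, optionally adding parents.
#' MZ co-twins share sex and age; DZ co-twins share age with independently
#' drawn sexes. Parent ages are the twins' age plus a generational offset.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex` ("F"/"M"), `role` (`mz_twin`, `dz_twin`, `parent`),
#'   `zygosity` (`MZ`, `DZ` or `NA` for non-twins) and `age` (years).
#' @export
simulate_pedigree <- function(config) {
  with_seed(config$seed, {
    n_fam <- config$n_mz_pairs + config$n_dz_pairs
    zyg <- rep(c("MZ", "DZ"), c(config$n_mz_pairs, config$n_dz_pairs))
    fam_id <- sprintf("fam%04d", seq_len(n_fam))

    draw_age <- function(n) {
      a <- rnorm(n, config$age_mean, config$age_sd)
      while (any(bad <- a < config$age_range[1] | a > config$age_range[2])) {
        a[bad] <- rnorm(sum(bad), config$age_mean, config$age_sd)
      }
      round(a, 1)
    }
    twin_age <- draw_age(n_fam)

    rows <- purrr::map_dfr(seq_len(n_fam), function(i) {
      if (zyg[i] == "MZ") {
        sx <- rep(if (runif(1) < config$prop_female) "F" else "M", 2)
      } else {
        sx <- ifelse(runif(2) < config$prop_female, "F", "M")
      }
      tibble(family_id = fam_id[i],
             sample_id = paste0(fam_id[i], "_t", 1:2),
             father_id = paste0(fam_id[i], "_fa"),
             mother_id = paste0(fam_id[i], "_mo"),
             sex = sx,
             role = if (zyg[i] == "MZ") "mz_twin" else "dz_twin",
             zygosity = zyg[i],
             age = twin_age[i])
    })

    if (config$n_parents > 0) {
      n_par_fam <- ceiling(config$n_parents / 2)
      assert_that(n_par_fam <= n_fam, "more parents requested than families")
      par_rows <- purrr::map_dfr(seq_len(n_par_fam), function(i) {
        ids <- c(paste0(fam_id[i], "_fa"), paste0(fam_id[i], "_mo"))
        tibble(family_id = fam_id[i], sample_id = ids,
               father_id = "0", mother_id = "0",
               sex = c("M", "F"), role = "parent", zygosity = NA_character_,
               age = round(twin_age[i] + rnorm(2, 28, 3), 1))
      })
      par_rows <- head(par_rows, config$n_parents)
      rows <- dplyr::bind_rows(rows, par_rows)
    }

    # parent ids not present in the sample are marked unknown ("0")
    rows$father_id[!rows$father_id %in% rows$sample_id] <- "0"
    rows$mother_id[!rows$mother_id %in% rows$sample_id] <- "0"
    rows
  })
}

#' Simulate per-sample covariates
#'
#' Adds the nuisance covariates the residualization stage corrects for:
#' measured white-blood-cell percentages (neutrophils, monocytes,
#' eosinophils), array row and sample plate, next to sex (coded 0 = male,
#' 1 = female) and age taken from the pedigree.
#'
#' @param ped Pedigree tibble from [simulate_pedigree()].
#' @param config A [sim_config()].
#' @return Tibble with one row per sample.
#' @export
simulate_covariates <- function(ped, config) {
  check_pedigree(ped)
  with_seed(if (is.null(config$seed)) NULL else child_seed(config$seed, 7), {
    n <- nrow(ped)
    tibble(sample_id = ped$sample_id,
           sex = as.integer(ped$sex == "F"),
           age = ped$age,
           neutrophil_pct = pmax(rnorm(n, 55, 8), 20),
           monocyte_pct = pmax(rnorm(n, 8, 2), 1),
           eosinophil_pct = pmax(rnorm(n, 3, 1.5), 0.1),
           array_row = factor(sample(paste0("R", 1:6), n, replace = TRUE)),
           plate = factor(sample(paste0("P", 1:8), n, replace = TRUE)))
  })
}

#' Simulate genotypes by gene dropping
#'
#' Founder genotypes are drawn under Hardy-Weinberg equilibrium at
#' minor-allele frequencies sampled from `config$maf_range`; offspring
#' receive one allele from each (possibly latent) parent by Mendelian
#' transmission. MZ co-twins are genotypically identical; DZ co-twins share
#' alleles through transmission, realising the identity-by-descent structure
#' the two-GRM model assumes.
#'
#' @param ped Pedigree tibble from [simulate_pedigree()].
#' @param config A [sim_config()].
#' @return List with `dosage` (samples x SNPs matrix of 0/1/2) and
#'   `snp_info` (tibble: id, chrom, pos, maf).
#' @export
simulate_genotypes <- function(ped, config) {
  check_pedigree(ped)
  with_seed(if (is.null(config$seed)) NULL else child_seed(config$seed, 11), {
    S <- config$n_snps
    maf <- runif(S, config$maf_range[1], config$maf_range[2])
    snp_info <- tibble(id = sprintf("snp%05d", seq_len(S)),
                       chrom = sample(1:22, S, replace = TRUE),
                       pos = sample.int(5e7, S, replace = TRUE),
                       maf = maf)

    fams <- split(ped, ped$family_id)
    rows <- vector("list", length(fams))
    names(rows) <- names(fams)
    for (fam in names(fams)) {
      fd <- fams[[fam]]
      # latent founder genotypes for this family under HWE
      father <- rbinom(S, 2, maf)
      mother <- rbinom(S, 2, maf)
      transmit <- function(g) rbinom(S, 1, g / 2)
      twins <- fd[fd$role %in% c("mz_twin", "dz_twin"), ]
      geno <- matrix(NA_integer_, nrow = nrow(fd), ncol = S,
                     dimnames = list(fd$sample_id, snp_info$id))
      if (nrow(twins) > 0) {
        first <- transmit(father) + transmit(mother)
        if (all(twins$zygosity == "MZ", na.rm = TRUE)) {
          for (id in twins$sample_id) geno[id, ] <- first
        } else {
          geno[twins$sample_id[1], ] <- first
          for (id in twins$sample_id[-1]) {
            geno[id, ] <- transmit(father) + transmit(mother)
          }
        }
      }
      pars <- fd[fd$role == "parent", ]
      if (nrow(pars) > 0) {
        for (j in seq_len(nrow(pars))) {
          geno[pars$sample_id[j], ] <- if (pars$sex[j] == "M") father else mother
        }
      }
      rows[[fam]] <- geno
    }
    dosage <- do.call(rbind, rows)[ped$sample_id, , drop = FALSE]
    list(dosage = dosage, snp_info = snp_info)
  })
}

# expected additive relatedness block for one family (diag 1, MZ 1,
# sib/DZ and parent-offspring 0.5) and dominance block (MZ 1, sib/DZ 0.25)
family_blocks <- function(fd) {
  n <- nrow(fd)
  A <- diag(n); D <- diag(n)
  dimnames(A) <- dimnames(D) <- list(fd$sample_id, fd$sample_id)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      twins_ij <- fd$role[c(i, j)] %in% c("mz_twin", "dz_twin")
      if (all(twins_ij)) {
        if (all(fd$zygosity[c(i, j)] == "MZ", na.rm = TRUE)) {
          A[i, j] <- 1; D[i, j] <- 1
        } else {
          A[i, j] <- 0.5; D[i, j] <- 0.25
        }
      } else if (any(fd$role[c(i, j)] == "parent") && any(twins_ij)) {
        A[i, j] <- 0.5   # parent-offspring; no dominance sharing
      }                  # parent-parent: unrelated
    }
  }
  list(A = A, D = D)
}

# draw one multivariate-normal deviate per family with covariance
# vc * block; blocks may be singular (MZ), so use an eigen square root
rmvnorm_blocks <- function(ped, vc, which = c("A", "D")) {
  which <- match.arg(which)
  out <- setNames(numeric(nrow(ped)), ped$sample_id)
  if (vc <= 0) return(out)
  for (fd in split(ped, ped$family_id)) {
    B <- family_blocks(fd)[[which]]
    ev <- eigen(B, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(B))
    out[fd$sample_id] <- sqrt(vc) * as.numeric(L %*% rnorm(nrow(B)))
  }
  out
}

#' Simulate one methylation site with known variance partition
#'
#' Generates per-sample values on the (standardised) M scale as the sum of a
#' SNP-tagged additive score, an untagged polygenic deviate, a family-shared
#' common environmental deviate, a dominance deviate and a unique
#' environmental deviate, with the stated variance fractions at moderator
#' value zero. Moderation multiplies the polygenic and unique-environmental
#' standard deviations by `(sigma + beta * m) / sigma`, where `m` is the
#' z-scored age and/or the 0/1 sex code.
#'
#' @param ped Pedigree tibble.
#' @param genotypes Result of [simulate_genotypes()].
#' @param covariates Tibble from [simulate_covariates()] (needs `sex`, `age`).
#' @param params One row of [site_params()].
#' @param seed Integer seed.
#' @return Named numeric vector of site values (one per sample).
#' @export
simulate_site <- function(ped, genotypes, covariates, params, seed = NULL) {
  check_pedigree(ped)
  params <- as.list(params[1, ])
  with_seed(seed, {
    n <- nrow(ped)
    age_z <- as.numeric(scale(covariates$age))
    sex01 <- covariates$sex

    g_snp <- setNames(numeric(n), ped$sample_id)
    if (params$var_snp > 0) {
      assert_that(params$n_causal >= 1, "var_snp > 0 requires n_causal >= 1")
      idx <- sample.int(ncol(genotypes$dosage), params$n_causal)
      w <- rnorm(params$n_causal)
      score <- as.numeric(genotypes$dosage[, idx, drop = FALSE] %*% w)
      s <- sd(score)
      assert_that(s > 0, "causal score has zero variance; increase n_causal or MAF")
      g_snp[] <- (score - mean(score)) / s * sqrt(params$var_snp)
    }

    g_ped <- rmvnorm_blocks(ped, params$var_ped, "A")
    d_dev <- rmvnorm_blocks(ped, params$var_d, "D")
    c_fam <- setNames(numeric(n), ped$sample_id)
    if (params$var_c > 0) {
      fam_draw <- rnorm(length(unique(ped$family_id)), 0, sqrt(params$var_c))
      names(fam_draw) <- unique(ped$family_id)
      c_fam[] <- fam_draw[ped$family_id]
    }
    e_dev <- rnorm(n, 0, sqrt(params$var_e))

    mod_factor <- function(sigma, slope_age, slope_sex) {
      if (sigma == 0) {
        assert_that(slope_age == 0 && slope_sex == 0,
                    "moderation slope on a zero-variance component")
        return(rep(1, n))
      }
      s_m <- sigma + slope_age * age_z + slope_sex * sex01
      assert_that(all(s_m > 0),
                  "moderated standard deviation is non-positive over the sampled moderator range")
      s_m / sigma
    }
    fac_g <- mod_factor(sqrt(params$var_ped), params$beta_g_age, params$beta_g_sex)
    fac_e <- mod_factor(sqrt(params$var_e), params$beta_e_age, params$beta_e_sex)

    g_snp + g_ped * fac_g + c_fam + d_dev + e_dev * fac_e
  })
}

#' Simulate a full methylome with ground truth
#'
#' @inheritParams simulate_site
#' @param site_params Tibble of per-site parameters (one row per site).
#' @param seed Integer seed; per-site child seeds are derived from it.
#' @return List with `m` (sites x samples matrix on the M scale) and
#'   `truth` (the site parameter tibble, with site ids filled in).
#' @export
simulate_methylome <- function(ped, genotypes, covariates, site_params,
                               seed = NULL) {
  ids <- site_params$site_id
  if (all(is.na(ids))) ids <- sprintf("cg%06d", seq_len(nrow(site_params)))
  m <- matrix(NA_real_, nrow(site_params), nrow(ped),
              dimnames = list(ids, ped$sample_id))
  for (i in seq_len(nrow(site_params))) {
    s_i <- if (is.null(seed)) NULL else child_seed(seed, 100 + i)
    m[i, ] <- simulate_site(ped, genotypes, covariates, site_params[i, ], s_i)
  }
  truth <- site_params
  truth$site_id <- ids
  list(m = m, truth = truth)
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs the full generator and writes TSV files: pedigree, genotype dosages
#' with a SNP metadata sidecar, methylation on both the M and beta scales,
#' per-sample covariates, and a truth table holding every per-site
#' generative parameter. Beta values are obtained from the simulated
#' (standardised) M values by the inverse log2-logistic transform shifted to
#' each site's baseline methylation proportion, so they always lie in (0, 1).
#' Missing cells are injected completely at random at `config$missing_rate`.
#'
#' @param config A [sim_config()]; its `seed` fixes all output.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
generate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped <- simulate_pedigree(config)
  covars <- simulate_covariates(ped, config)
  geno <- simulate_genotypes(ped, config)
  sim <- simulate_methylome(ped, geno, covars, config$site_params,
                            seed = config$seed)

  m <- sim$m
  if (config$missing_rate > 0) {
    mask <- with_seed(if (is.null(config$seed)) NULL else child_seed(config$seed, 13),
                      matrix(runif(length(m)) < config$missing_rate,
                             nrow(m), ncol(m)))
    m[mask] <- NA_real_
  }
  m0 <- log2(sim$truth$baseline_beta / (1 - sim$truth$baseline_beta))
  beta <- beta_from_m(sweep(m, 1, m0, `+`))
  dimnames(beta) <- dimnames(m)

  paths <- list(
    pedigree = file.path(dir, "pedigree.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    snp_info = file.path(dir, "snp_info.tsv"),
    methylation_m = file.path(dir, "methylation_m.tsv"),
    methylation_beta = file.path(dir, "methylation_beta.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    truth = file.path(dir, "truth.tsv"))

  readr::write_tsv(ped, paths$pedigree)
  readr::write_tsv(tibble::rownames_to_column(
    as.data.frame(geno$dosage), "sample_id"), paths$genotypes)
  readr::write_tsv(geno$snp_info, paths$snp_info)
  write_meth_matrix(m, paths$methylation_m)
  write_meth_matrix(beta, paths$methylation_beta)
  readr::write_tsv(covars, paths$covariates)
  readr::write_tsv(sim$truth, paths$truth)

  invisible(list(pedigree = ped, covariates = covars, genotypes = geno,
                 methylation_m = m, methylation_beta = beta,
                 truth = sim$truth, paths = paths))
}

#' Read and write methylation matrices as TSV
#'
#' Sites x samples matrices are stored with a `site_id` first column and one
#' column per sample.
#'
#' @param meth Sites x samples numeric matrix.
#' @param path File path.
#' @return `read_meth_matrix()` returns the matrix; `write_meth_matrix()`
#'   returns `path` invisibly.
#' @export
write_meth_matrix <- function(meth, path) {
  check_meth_matrix(meth)
  df <- tibble::rownames_to_column(as.data.frame(meth), "site_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_meth_matrix
#' @export
read_meth_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
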