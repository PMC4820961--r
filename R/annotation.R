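#' Assign sites to gene-centric regions
#'
#' Each site is assigned to the region of its nearest transcription start
#' site (TSS), with windows oriented by gene strand and measured on 1-based
#' coordinates: proximal promoter (-1.5 kb to +500 bp of the TSS), distal
#' promoter (-10 kb to -1.5 kb), gene body (+500 bp to the 3' end),
#' downstream (3' end to +5 kb past it), and intergenic otherwise
#' (in particular, any site more than 10 kb upstream of the nearest TSS).
#' Boundary positions belong to the more promoter-proximal class; ties
#' between equidistant TSSs are broken by the lexicographically smaller
#' gene id.
#'
#' @param sites Tibble with `site_id`, `chrom`, `pos` (1-based).
#' @param genes Tibble with `gene_id`, `chrom`, `strand` ("+"/"-"), `tss`,
#'   `end` (the 3' end position).
#' @return Character vector of region labels (`proximal_promoter`,
#'   `distal_promoter`, `gene_body`, `downstream`, `intergenic`), one per
#'   site.
#' @export
assign_gene_region <- function(sites, genes) {
  assert_that(all(c("chrom", "pos") %in% names(sites)),
              "`sites` needs `chrom` and `pos`")
  assert_that(all(c("gene_id", "chrom", "strand", "tss", "end") %in% names(genes)),
              "`genes` needs gene_id, chrom, strand, tss, end")
  vapply(seq_len(nrow(sites)), function(i) {
    g <- genes[genes$chrom == sites$chrom[i], ]
    if (nrow(g) == 0) {
      rlang::warn(paste0("chromosome ", sites$chrom[i],
                         " absent from gene annotation; labelled intergenic"))
      return("intergenic")
    }
    dist <- abs(sites$pos[i] - g$tss)
    g <- g[order(dist, g$gene_id), ][1, ]
    # signed distance from the TSS in the gene's reading direction
    d <- if (g$strand == "+") sites$pos[i] - g$tss else g$tss - sites$pos[i]
    gene_len <- abs(g$end - g$tss)
    if (d >= -1500 && d <= 500) "proximal_promoter"
    else if (d >= -10000 && d < -1500) "distal_promoter"
    else if (d > 500 && d <= gene_len) "gene_body"
    else if (d > gene_len && d <= gene_len + 5000) "downstream"
    else "intergenic"
  }, character(1))
}

#' Assign sites to CpG-island-centric regions
#'
#' A site inside a CpG island (CGI) is `island`; within 2 kb of the nearest
#' island edge, `shore`; within the next 2 kb (2-4 kb from the edge),
#' `shelf`; otherwise `non_cgi`. Coordinates are 1-based inclusive.
#'
#' @param sites Tibble with `chrom` and `pos`.
#' @param cgis Tibble with `chrom`, `start`, `end` (1-based inclusive,
#'   non-overlapping per chromosome).
#' @return Character vector of labels (`island`, `shore`, `shelf`,
#'   `non_cgi`).
#' @export
assign_cgi_region <- function(sites, cgis) {
  assert_that(all(c("chrom", "start", "end") %in% names(cgis)),
              "`cgis` needs chrom, start, end")
  vapply(seq_len(nrow(sites)), function(i) {
    cg <- cgis[cgis$chrom == sites$chrom[i], ]
    if (nrow(cg) == 0) return("non_cgi")
    pos <- sites$pos[i]
    inside <- pos >= cg$start & pos <= cg$end
    if (any(inside)) return("island")
    edge_dist <- min(pmin(abs(pos - cg$start), abs(pos - cg$end)))
    if (edge_dist <= 2000) "shore"
    else if (edge_dist <= 4000) "shelf"
    else "non_cgi"
  }, character(1))
}

#' Read BED intervals (0-based half-open) into 1-based inclusive tibbles
#'
#' @param path BED file path (chrom, start, end, optional name).
#' @return Tibble with `chrom`, `start`, `end` on 1-based inclusive
#'   coordinates.
#' @export
read_bed_intervals <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#")
  tibble(chrom = as.character(df[[1]]), start = df[[2]] + 1, end = df[[3]])
}

#' Test a sequence against the CpG-island criteria
#'
#' A CpG island requires GC content above 50 percent, length above 200 bp,
#' and an observed/expected CpG ratio above 0.6, where observed is the
#' count of CG dinucleotides and expected is `(#C * #G) / length`; all
#' three comparisons are strict.
#'
#' @param sequence A character string over A/C/G/T (or a
#'   `Biostrings::DNAString`).
#' @return List with `is_cgi`, `gc_fraction`, `length`, `obs_exp_cpg`.
#' @export
check_cgi_criteria <- function(sequence) {
  s <- toupper(as.character(sequence))
  assert_that(grepl("^[ACGT]*$", s), "sequence contains ambiguous bases")
  len <- nchar(s)
  assert_that(len > 0, "empty sequence")
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    dna <- Biostrings::DNAString(s)
    freq <- Biostrings::letterFrequency(dna, c("C", "G"))
    n_c <- freq[["C"]]; n_g <- freq[["G"]]
    obs <- Biostrings::countPattern("CG", dna)
  } else {
    chars <- strsplit(s, "")[[1]]
    n_c <- sum(chars == "C"); n_g <- sum(chars == "G")
    obs <- sum(chars[-len] == "C" & chars[-1] == "G")
  }
  gc <- (n_c + n_g) / len
  expd <- n_c * n_g / len
  oe <- if (expd > 0) obs / expd else 0
  list(is_cgi = gc > 0.5 && len > 200 && oe > 0.6,
       gc_fraction = gc, length = len, obs_exp_cpg = oe)
}

#' Categorize sites by variability, heritability and stability
#'
#' Flags per site: `variable` (s.d. of the methylation proportion strictly
#' above 0.03), `high_h2` (h2 at least 0.5) / `low_h2` (below 0.2), the
#' analogous SNP-heritability flags, and longitudinal stability
#' (`stable` when the longitudinal correlation is at least 0.5, `unstable`
#' below 0.2).
#'
#' @param catalogue Tibble with `site_id` and heritability columns `h2_ibd`
#'   and (optionally) `h2_snps`.
#' @param sd_beta Named numeric vector (or tibble `site_id`/`sd_beta`) of
#'   per-site standard deviations of the methylation proportion.
#' @param longitudinal_r Optional named vector or tibble of per-site
#'   longitudinal correlations.
#' @return Tibble of per-site logical flags.
#' @export
categorize_sites <- function(catalogue, sd_beta = NULL, longitudinal_r = NULL) {
  assert_that("site_id" %in% names(catalogue) && "h2_ibd" %in% names(catalogue),
              "catalogue needs `site_id` and `h2_ibd` columns")
  pull_named <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) setNames(x[[2]], x[[1]]) else x
  }
  sd_beta <- pull_named(sd_beta)
  longitudinal_r <- pull_named(longitudinal_r)
  out <- tibble(site_id = catalogue$site_id,
                high_h2 = catalogue$h2_ibd >= 0.5,
                low_h2 = catalogue$h2_ibd < 0.2)
  if ("h2_snps" %in% names(catalogue)) {
    out$high_h2snp <- catalogue$h2_snps >= 0.5
    out$low_h2snp <- catalogue$h2_snps < 0.2
  }
  if (!is.null(sd_beta)) {
    out$variable <- unname(sd_beta[out$site_id] > 0.03)
  }
  if (!is.null(longitudinal_r)) {
    r <- unname(longitudinal_r[out$site_id])
    out$longitudinally_stable <- r >= 0.5
    out$longitudinally_unstable <- r < 0.2
  }
  out
}

#' Chi-square enrichment of a site category across annotation classes
#'
#' For each annotation class, builds the 2x2 table of (in category) x
#' (in class) over the background and applies Pearson's chi-square test
#' without continuity correction, with Bonferroni control over the family
#' of annotation tests.
#'
#' @param category_sites Character vector of site ids in the category
#'   (must be a subset of the background).
#' @param background_sites Character vector of all site ids considered.
#' @param annotation Named character vector (or tibble `site_id`/label) of
#'   class labels covering the background.
#' @param family_size Number of tests in the Bonferroni family
#'   (default 117).
#' @param alpha Family-wise error rate (default 0.05).
#' @param correct Apply continuity correction (default `FALSE`).
#' @return Tibble: `class`, `n_category`, `n_background`, `chi2`, `p`,
#'   `direction` (`enriched`/`depleted`), `significant`.
#' @export
enrichment_test <- function(category_sites, background_sites, annotation,
                            family_size = 117, alpha = 0.05,
                            correct = FALSE) {
  assert_that(length(category_sites) > 0, "category is empty")
  assert_that(all(category_sites %in% background_sites),
              "category must be a subset of the background")
  if (is.data.frame(annotation)) {
    annotation <- setNames(annotation[[2]], annotation[[1]])
  }
  ann <- annotation[background_sites]
  assert_that(!anyNA(ann), "annotation must cover every background site")
  in_cat <- background_sites %in% category_sites
  thr <- multiple_testing_threshold(alpha, family_size)
  purrr::map_dfr(sort(unique(ann)), function(cl) {
    in_cl <- ann == cl
    tab <- table(factor(in_cat, c(TRUE, FALSE)), factor(in_cl, c(TRUE, FALSE)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    p_cat <- mean(in_cl[in_cat]); p_bg <- mean(in_cl)
    tibble(class = cl,
           n_category = sum(in_cl & in_cat), n_background = sum(in_cl),
           chi2 = unname(ct$statistic), p = ct$p.value,
           direction = if (p_cat > p_bg) "enriched" else "depleted",
           significant = ct$p.value < thr)
  })
}
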