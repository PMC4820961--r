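#' Probe-level quality-control filters
#'
#' Applies the standard 450k probe filters in a fixed order: (1) blacklisted
#' probes (ambiguously mapped, or with a SNP at the interrogated CpG) are
#' removed globally; (2) individual cells failing detection
#' (`detection_p > detp_max`), bead count (`bead_count < min_beads`) or a
#' zero-intensity flag are set missing; (3) probes whose success rate across
#' samples falls below `min_success` are dropped.
#'
#' @param meth Sites x samples numeric matrix (beta or M scale).
#' @param detection_p,bead_count,intensity_zero Optional per-cell matrices
#'   with the same dimnames as `meth` (detection p-values, bead counts, and
#'   logical zero-intensity flags).
#' @param blacklist_ambiguous,blacklist_snp_at_cpg Character vectors of site
#'   ids removed regardless of QC values.
#' @param detp_max Detection p-value ceiling (default 0.01).
#' @param min_beads Minimum bead count (default 3).
#' @param min_success Minimum per-probe success rate across samples
#'   (default 0.95).
#' @return List with `meth` (the filtered matrix, failed cells `NA`) and
#'   `report`, itself a list of `probe_removals` (tibble of counts by
#'   reason) and `sample_success` (tibble of per-sample success rates over
#'   retained probes).
#' @export
apply_probe_filters <- function(meth, detection_p = NULL, bead_count = NULL,
                                intensity_zero = NULL,
                                blacklist_ambiguous = character(),
                                blacklist_snp_at_cpg = character(),
                                detp_max = 0.01, min_beads = 3,
                                min_success = 0.95) {
  check_meth_matrix(meth)
  assert_that(detp_max >= 0 && detp_max <= 1, "`detp_max` must be in [0, 1]")
  assert_that(min_success >= 0 && min_success <= 1,
              "`min_success` must be in [0, 1]")
  check_shape <- function(x, what) {
    if (!is.null(x)) {
      assert_that(identical(dim(x), dim(meth)),
                  paste0("`", what, "` must match the methylation matrix shape"))
    }
    x
  }
  check_shape(detection_p, "detection_p")
  check_shape(bead_count, "bead_count")
  check_shape(intensity_zero, "intensity_zero")

  n_total <- nrow(meth)
  black <- union(blacklist_ambiguous, blacklist_snp_at_cpg)
  n_ambiguous <- sum(rownames(meth) %in% blacklist_ambiguous)
  n_snp_cpg <- sum(rownames(meth) %in% setdiff(blacklist_snp_at_cpg,
                                               blacklist_ambiguous))
  meth <- meth[!rownames(meth) %in% black, , drop = FALSE]
  sub <- function(x) if (is.null(x)) NULL else x[rownames(meth), , drop = FALSE]
  detection_p <- sub(detection_p); bead_count <- sub(bead_count)
  intensity_zero <- sub(intensity_zero)

  fail <- matrix(FALSE, nrow(meth), ncol(meth))
  if (!is.null(detection_p)) fail <- fail | (!is.na(detection_p) & detection_p > detp_max)
  if (!is.null(bead_count)) fail <- fail | (!is.na(bead_count) & bead_count < min_beads)
  if (!is.null(intensity_zero)) fail <- fail | (intensity_zero %in% TRUE)
  dim(fail) <- dim(meth)
  meth[fail] <- NA_real_

  success <- rowMeans(!is.na(meth))
  low <- success < min_success
  kept <- meth[!low, , drop = FALSE]

  report <- list(
    probe_removals = tibble(
      reason = c("ambiguous_mapping", "snp_at_cpg", "low_success_rate"),
      n_probes = c(n_ambiguous, n_snp_cpg, sum(low))),
    cells_failed = sum(fail),
    sample_success = tibble(
      sample_id = colnames(kept),
      success_rate = if (nrow(kept)) colMeans(!is.na(kept)) else NA_real_),
    n_probes_in = n_total, n_probes_out = nrow(kept))
  list(meth = kept, report = report)
}

#' Count unclear genotype calls from SNP control probes
#'
#' The 450k array carries 65 SNP probes whose allele-signal proportions
#' cluster near 0, 0.5 and 1 in uncontaminated samples. A proportion inside
#' \[0.2, 0.4\] or \[0.6, 0.8\] (closed intervals) is an "unclear" genotype;
#' a sample with at least `exclude_at` unclear genotypes is flagged for
#' exclusion as likely contaminated.
#'
#' @param props Numeric vector of allele-signal proportions in \[0, 1\]
#'   (conventionally of length 65).
#' @param exclude_at Exclusion threshold on the count (default 15).
#' @return List with `n_unclear` and logical `exclude`.
#' @export
count_unclear_genotypes <- function(props, exclude_at = 15) {
  assert_that(all(props >= 0 & props <= 1, na.rm = TRUE),
              "proportions must lie in [0, 1]")
  n <- sum((props >= 0.2 & props <= 0.4) | (props >= 0.6 & props <= 0.8),
           na.rm = TRUE)
  list(n_unclear = n, exclude = n >= exclude_at)
}

#' Screen all samples for contamination
#'
#' @param props_matrix Samples x probes matrix of allele-signal proportions.
#' @inheritParams count_unclear_genotypes
#' @return Tibble with `sample_id`, `n_unclear`, `exclude`.
#' @export
contamination_screen <- function(props_matrix, exclude_at = 15) {
  res <- apply(props_matrix, 1, count_unclear_genotypes,
               exclude_at = exclude_at)
  tibble(sample_id = rownames(props_matrix) %||%
           as.character(seq_len(nrow(props_matrix))),
         n_unclear = vapply(res, function(r) as.numeric(r$n_unclear),
                            numeric(1), USE.NAMES = FALSE),
         exclude = vapply(res, `[[`, logical(1), "exclude",
                          USE.NAMES = FALSE))
}

#' Impute missing methylation values
#'
#' `site_mean` replaces each missing cell with the site's mean across
#' observed samples (deterministic). `knn` replaces it with the average of
#' the `k` most similar sites (Euclidean distance over shared observed
#' samples), the usual nearest-neighbour scheme for methylation arrays.
#'
#' @param meth Sites x samples matrix with missing cells.
#' @param method `"site_mean"` (default) or `"knn"`.
#' @param k Number of neighbour sites for `knn`.
#' @return List with `meth` (complete matrix) and `imputed` (logical mask of
#'   cells that were filled in).
#' @export
impute_missing <- function(meth, method = c("site_mean", "knn"), k = 10) {
  check_meth_matrix(meth)
  method <- match.arg(method)
  miss <- is.na(meth)
  frac <- rowMeans(miss)
  assert_that(all(frac < 1),
              paste0("site(s) with all values missing: ",
                     paste(head(rownames(meth)[frac == 1]), collapse = ", ")))
  assert_that(all(frac < 0.5), "sites with >= 50% missing values present")
  if (!any(miss)) return(list(meth = meth, imputed = miss))

  if (method == "site_mean") {
    mu <- rowMeans(meth, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    meth[idx] <- mu[idx[, 1]]
  } else {
    assert_that(k < nrow(meth), "`k` must be smaller than the number of sites")
    # distances between sites over pairwise-complete samples
    D <- as.matrix(stats::dist(meth))
    for (i in which(rowSums(miss) > 0)) {
      nb <- order(D[i, ])[-1]
      for (j in which(miss[i, ])) {
        donors <- nb[!is.na(meth[nb, j])]
        donors <- head(donors, k)
        assert_that(length(donors) > 0, "no donor sites for knn imputation")
        meth[i, j] <- mean(meth[donors, j])
      }
    }
  }
  list(meth = meth, imputed = miss)
}
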