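#' Build the covariate design used for residual correction
#'
#' Assembles the standard correction set — sex, age, array row, plate
#' (dummy coded), white-blood-cell percentages — optionally extended with
#' genotype principal components. Analyses that use genome-wide SNP data are
#' run on residuals that include the genotype PCs; all other analyses (twin
#' correlations and models, longitudinal and cross-tissue comparisons) omit
#' them.
#'
#' @param covariates Tibble with columns `sample_id`, `sex`, `age`,
#'   `neutrophil_pct`, `monocyte_pct`, `eosinophil_pct`, `array_row`,
#'   `plate`.
#' @param genotype_pcs Optional samples x k matrix from [genotype_pcs()].
#' @return A data frame of covariates ready for [residualize()], with
#'   sample ids as row names.
#' @export
build_covariate_design <- function(covariates, genotype_pcs = NULL) {
  need <- c("sample_id", "sex", "age", "neutrophil_pct", "monocyte_pct",
            "eosinophil_pct", "array_row", "plate")
  assert_that(all(need %in% names(covariates)),
              paste0("covariates must contain: ", paste(need, collapse = ", ")))
  df <- as.data.frame(covariates[, setdiff(need, "sample_id")])
  rownames(df) <- covariates$sample_id
  if (!is.null(genotype_pcs)) {
    pcs <- genotype_pcs[covariates$sample_id, , drop = FALSE]
    df <- cbind(df, as.data.frame(pcs))
  }
  df
}

#' Residualize methylation values on covariates
#'
#' Fits per-site ordinary least squares of the methylation value on the
#' encoded design (with intercept) and returns the residuals, which are
#' orthogonal to every design column, plus the per-site fraction of
#' variance explained.
#'
#' @param meth Sites x samples matrix.
#' @param design Data frame of covariates with sample ids as row names
#'   (see [build_covariate_design()]); factors are dummy coded.
#' @return List with `meth` (residual matrix), `r2` (tibble: `site_id`,
#'   `r2`) and `mean_r2`.
#' @export
residualize <- function(meth, design) {
  check_meth_matrix(meth)
  assert_that(all(colnames(meth) %in% rownames(design)),
              "design must cover every sample in the methylation matrix")
  design <- design[colnames(meth), , drop = FALSE]
  X <- if (ncol(design) == 0) {
    matrix(1, ncol(meth), 1, dimnames = list(colnames(meth), "(Intercept)"))
  } else {
    model.matrix(~ ., data = design)
  }
  assert_that(ncol(meth) > ncol(X),
              "more design columns than samples")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    rlang::abort(paste0("rank-deficient design; collinear columns: ",
                        paste(drop_cols, collapse = ", ")))
  }
  Y <- t(meth)                              # samples x sites
  fitted <- qr.fitted(qrX, Y)
  res <- Y - fitted
  tot <- colSums(scale(Y, scale = FALSE)^2)
  rss <- colSums(res^2)
  r2 <- ifelse(tot > 0, 1 - rss / tot, 0)
  out <- t(res)
  dimnames(out) <- dimnames(meth)
  list(meth = out,
       r2 = tibble(site_id = rownames(meth), r2 = unname(r2)),
       mean_r2 = mean(r2))
}

#' Z-standardize each methylation site
#'
#' Centers and scales every site to mean 0, standard deviation 1.
#'
#' @param meth Sites x samples matrix; all sites must have positive
#'   standard deviation.
#' @return Standardized matrix of the same shape.
#' @export
zstandardize <- function(meth) {
  check_meth_matrix(meth)
  s <- apply(meth, 1, sd, na.rm = TRUE)
  bad <- which(!is.finite(s) | s == 0)
  assert_that(length(bad) == 0,
              paste0("zero-variance site(s): ",
                     paste(head(rownames(meth)[bad]), collapse = ", ")))
  mu <- rowMeans(meth, na.rm = TRUE)
  (meth - mu) / s
}

#' Per-site association with a covariate, cluster-robust by family
#'
#' Regresses each site on a single covariate and tests the slope with a
#' family-clustered sandwich standard error (robust z-test), the working
#' form of a GEE with independence working correlation.
#'
#' @param meth Sites x samples matrix.
#' @param covariate Numeric vector, one value per sample (matrix column
#'   order).
#' @param family_id Character/factor vector of family memberships used as
#'   clusters.
#' @return Tibble: `site_id`, `slope`, `se`, `z`, `p`.
#' @export
site_covariate_association <- function(meth, covariate, family_id) {
  check_meth_matrix(meth)
  assert_that(length(covariate) == ncol(meth) &&
              length(family_id) == ncol(meth),
              "covariate and family_id must have one entry per sample")
  assert_that(sd(covariate) > 0, "covariate is constant")
  assert_that(length(unique(family_id)) >= 2, "need at least two families")
  fam <- factor(family_id)
  res <- purrr::map_dfr(seq_len(nrow(meth)), function(i) {
    y <- meth[i, ]
    ok <- !is.na(y)
    fit <- lm(y[ok] ~ covariate[ok])
    vc <- sandwich::vcovCL(fit, cluster = fam[ok], type = "HC0",
                           cadjust = FALSE)
    b <- coef(fit)[2]
    se <- sqrt(vc[2, 2])
    z <- b / se
    tibble(site_id = rownames(meth)[i], slope = unname(b), se = se,
           z = unname(z), p = 2 * pnorm(-abs(unname(z))))
  })
  res
}
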