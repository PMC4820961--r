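#' Fit the two-GRM variance-components model for one site
#'
#' Maximum-likelihood fit of the mixed model in which the covariance of the
#' (covariate-adjusted, standardized) methylation value between individuals
#' is \deqn{V = A_{IBS}\,\sigma^2_{SNP} + A_{IBD}\,\sigma^2_{A-SNP} +
#' I\,\sigma^2_e,} with a free intercept. The first GRM carries the
#' SNP-tagged genetic variance shared by all (even distantly related)
#' individuals; the second, in which distant relationships are zeroed,
#' carries the additional genetic variance shared only by close relatives —
#' the difference between total additive genetic variance and the variance
#' explained by genotyped SNPs. Derived quantities:
#' `h2_ibd = (s2_snp + s2_ped) / (s2_snp + s2_ped + s2_e)` and
#' `h2_snps = s2_snp / (s2_snp + s2_ped + s2_e)`, so `h2_snps <= h2_ibd`
#' always.
#'
#' Variances are optimised on the log scale (quasi-Newton with analytic
#' gradients), which enforces non-negativity; a component driven to the
#' lower bound is reported as a boundary. Standard errors come from the
#' numerically evaluated observed information on the variance scale.
#'
#' @param y Named numeric vector of standardized site values.
#' @param A_ibs [grm()] of kind `ibs` (or a plain matrix).
#' @param A_ibd [grm()] of kind `ibd_thresholded` or `pedigree_expected`
#'   (or a plain matrix).
#' @param fix_snp_zero If `TRUE`, drop the SNP term (sets
#'   `sigma2_snp` to 0); used to reproduce the classical twin AE model with
#'   a pedigree GRM.
#' @param reml Use residual maximum likelihood instead of ML.
#' @param n_restarts Extra random starts beyond the moment-based one.
#' @return Object of class `two_grm_fit`.
#' @export
fit_two_grm <- function(y, A_ibs, A_ibd, fix_snp_zero = FALSE, reml = FALSE,
                        n_restarts = 0) {
  M1 <- as_grm_matrix(A_ibs); M2 <- as_grm_matrix(A_ibd)
  n <- length(y)
  assert_that(all(dim(M1) == n) && all(dim(M2) == n),
              "GRM dimensions must match the phenotype length")
  if (!is.null(names(y)) && !is.null(rownames(M2))) {
    assert_that(identical(names(y), rownames(M2)),
                "sample ids of y and the GRMs disagree")
  }
  # thresholding an IBS GRM estimated from finitely many SNPs leaves mild
  # negative eigenvalues; only grossly indefinite inputs are rejected, and
  # the Cholesky factorisation guards every likelihood evaluation
  for (M in list(M1, M2)) {
    ev_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    assert_that(ev_min > -0.5 * sum(diag(M)) / n,
                "GRM is indefinite beyond tolerance")
  }
  kernels <- if (fix_snp_zero) list(M2, diag(n)) else list(M1, M2, diag(n))
  p <- length(kernels)
  lik <- make_vc_lik(y, kernels, reml = reml)

  vy <- var(y)
  lower <- rep(log(1e-10), p); upper <- rep(log(1e3), p)
  starts <- list(log(rep(vy / p, p)))
  for (r in seq_len(n_restarts)) {
    starts <- c(starts, list(log(runif(p, 0.05, 1) * vy)))
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, lik$nll, lik$grad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 200, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  assert_that(!is.null(best), "two-GRM optimisation failed")
  converged <- best$convergence == 0 && best$value < 1e9
  th <- exp(best$par)
  v <- numeric(3)                 # s2_snp, s2_ped, s2_e
  if (fix_snp_zero) v[2:3] <- th else v <- th
  boundary <- v < 1e-8

  # observed information on the variance scale for the free components
  free <- if (fix_snp_zero) 2:3 else 1:3
  nll_var <- function(vv) lik$nll(log(pmax(vv, 1e-12)))
  se <- rep(NA_real_, 3)
  H <- tryCatch(num_hessian(nll_var, v[free]), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    # a non-positive-definite observed information at the optimum means the
    # component split is not identified (e.g. the two GRMs coincide):
    # flag the fit and report no standard errors for the affected terms
    Hi <- if (rcond(H) > 1e-6) tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Hi)) {
      boundary <- boundary | TRUE
    } else {
      d <- diag(Hi)
      se[free] <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
      if (any(d <= 0)) boundary <- boundary | TRUE
    }
  }

  vt <- sum(v)
  structure(list(sigma2_snp = v[1], sigma2_ped = v[2], sigma2_e = v[3],
                 se_snp = se[1], se_ped = se[2], se_e = se[3],
                 h2_ibd = (v[1] + v[2]) / vt, h2_snps = v[1] / vt,
                 ratio_snp = heritability_ratios(v[1] / vt, (v[1] + v[2]) / vt),
                 mean = lik$mu(best$par),
                 loglik = -best$value, converged = converged,
                 boundary = boundary, fix_snp_zero = fix_snp_zero,
                 reml = reml, n = n),
            class = "two_grm_fit")
}

#' @export
print.two_grm_fit <- function(x, ...) {
  cat(sprintf(
    "<two_grm_fit: s2_snp=%.3f s2_ped=%.3f s2_e=%.3f h2_ibd=%.3f h2_snps=%.3f%s>\n",
    x$sigma2_snp, x$sigma2_ped, x$sigma2_e, x$h2_ibd, x$h2_snps,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Share of heritability explained by genotyped SNPs
#'
#' `h2_snps / h2_ibd`, defined only when the total heritability is at least
#' `h2_floor`; undefined values are returned as `NA` and excluded from
#' catalogue summaries.
#'
#' @param h2_snps SNP heritability, or a `two_grm_fit` object.
#' @param h2_ibd Total heritability (ignored when a fit is supplied).
#' @param h2_floor Smallest total heritability for which the ratio is
#'   reported.
#' @return Ratio in \[0, 1\], or `NA` when undefined.
#' @examples
#' heritability_ratios(0.07, 0.19)  # 0.368...
#' @export
heritability_ratios <- function(h2_snps, h2_ibd = NULL, h2_floor = 1e-6) {
  if (inherits(h2_snps, "two_grm_fit")) {
    h2_ibd <- h2_snps$h2_ibd; h2_snps <- h2_snps$h2_snps
  }
  ifelse(h2_ibd >= h2_floor, pmin(h2_snps / h2_ibd, 1), NA_real_)
}

#' Two-GRM fits for every site
#'
#' @param meth Sites x samples standardized matrix.
#' @param A_ibs,A_ibd GRMs as in [fit_two_grm()].
#' @param ... Passed to [fit_two_grm()].
#' @return Tibble, one row per site, with variance estimates, standard
#'   errors, `h2_ibd`, `h2_snps`, `ratio_snp` and a `status` column; sites
#'   whose fit fails are retained with `NA` estimates.
#' @export
fit_two_grm_sites <- function(meth, A_ibs, A_ibd, ...) {
  check_meth_matrix(meth)
  purrr::map_dfr(rownames(meth), function(sid) {
    fit <- tryCatch(fit_two_grm(meth[sid, ], A_ibs, A_ibd, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(site_id = sid, sigma2_snp = NA_real_,
                    sigma2_ped = NA_real_, sigma2_e = NA_real_,
                    se_snp = NA_real_, se_ped = NA_real_, se_e = NA_real_,
                    h2_ibd = NA_real_, h2_snps = NA_real_,
                    ratio_snp = NA_real_, status = "failed"))
    }
    tibble(site_id = sid, sigma2_snp = fit$sigma2_snp,
           sigma2_ped = fit$sigma2_ped, sigma2_e = fit$sigma2_e,
           se_snp = fit$se_snp, se_ped = fit$se_ped, se_e = fit$se_e,
           h2_ibd = fit$h2_ibd, h2_snps = fit$h2_snps,
           ratio_snp = fit$ratio_snp,
           status = if (fit$converged) "ok" else "not_converged")
  })
}

#' Check equivalence of the GRM-based and twin-based heritability
#'
#' For each site, fits (a) the classical AE twin model by maximum
#' likelihood on complete twin pairs and (b) the variance-components model
#' with the pedigree-expected relatedness matrix and the SNP term fixed at
#' zero, then compares the two heritability estimates.
#'
#' @param meth Sites x samples matrix (twin samples; residualized).
#' @param ped Pedigree tibble covering exactly the samples in `meth`.
#' @param min_pairs Passed to [fit_twin_model()].
#' @return List with `per_site` (tibble: `site_id`, `h2_twins`, `h2_ibd`),
#'   `correlation` and `mean_abs_diff`.
#' @export
twin_grm_equivalence_check <- function(meth, ped, min_pairs = 10) {
  check_meth_matrix(meth)
  assert_that(setequal(colnames(meth), ped$sample_id),
              "samples in the methylation matrix and pedigree disagree")
  ped <- ped[match(colnames(meth), ped$sample_id), ]
  A_ped <- pedigree_kinship(ped)
  per_site <- purrr::map_dfr(rownames(meth), function(sid) {
    vals <- meth[sid, ]
    ae <- fit_twin_model(twin_pairs(ped, vals), "AE", min_pairs)
    vc <- fit_two_grm(vals, A_ped, A_ped, fix_snp_zero = TRUE)
    tibble(site_id = sid, h2_twins = ae$a2, h2_ibd = vc$h2_ibd)
  })
  list(per_site = per_site,
       correlation = cor(per_site$h2_twins, per_site$h2_ibd),
       mean_abs_diff = mean(abs(per_site$h2_twins - per_site$h2_ibd)))
}
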