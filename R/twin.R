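#' Extract complete twin pairs for one site
#'
#' Pairs each family's two twins (ordered by sample id) and drops pairs
#' with a missing value in either member.
#'
#' @param ped Pedigree tibble.
#' @param values Named numeric vector of per-sample site values.
#' @return Tibble with `family_id`, `zygosity`, `value1`, `value2`.
#' @export
twin_pairs <- function(ped, values) {
  check_pedigree(ped)
  tw <- ped[ped$role %in% c("mz_twin", "dz_twin"), ]
  tw <- tw[order(tw$family_id, tw$sample_id), ]
  pairs <- tw |>
    dplyr::group_by(.data$family_id) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(zygosity = .data$zygosity[1],
                     id1 = .data$sample_id[1], id2 = .data$sample_id[2],
                     .groups = "drop")
  out <- tibble(family_id = pairs$family_id, zygosity = pairs$zygosity,
                value1 = unname(values[pairs$id1]),
                value2 = unname(values[pairs$id2]))
  out[complete.cases(out), ]
}

#' Twin correlations by zygosity
#'
#' Pearson correlation of co-twin values within MZ and within DZ pairs.
#'
#' @param pairs Tibble from [twin_pairs()].
#' @return List with `rmz`, `rdz`, `n_mz`, `n_dz`.
#' @export
twin_correlations <- function(pairs) {
  one <- function(z) {
    d <- pairs[pairs$zygosity == z, ]
    if (nrow(d) < 3) return(list(r = NA_real_, n = nrow(d)))
    assert_that(sd(d$value1) > 0 && sd(d$value2) > 0,
                paste0("zero variance among ", z, " twins; correlation undefined"))
    list(r = cor(d$value1, d$value2), n = nrow(d))
  }
  mz <- one("MZ"); dz <- one("DZ")
  list(rmz = mz$r, rdz = dz$r, n_mz = mz$n, n_dz = dz$n)
}

#' Falconer estimate of twin heritability
#'
#' The moment estimate `h2 = 2 * (rMZ - rDZ)`, returned unclamped with a
#' flag when it falls outside \[0, 1\].
#'
#' @param rmz,rdz MZ and DZ twin correlations, or pass the list returned by
#'   [twin_correlations()] as `rmz`.
#' @return List with `h2` and logical `out_of_range`.
#' @examples
#' falconer_h2(0.20, 0.09)  # 0.22
#' @export
falconer_h2 <- function(rmz, rdz = NULL) {
  if (is.list(rmz)) { rdz <- rmz$rdz; rmz <- rmz$rmz }
  h2 <- 2 * (rmz - rdz)
  list(h2 = h2, out_of_range = h2 < 0 | h2 > 1)
}

twin_model_components <- list(
  ACE = c("a2", "c2", "e2"), ADE = c("a2", "d2", "e2"),
  AE = c("a2", "e2"), CE = c("c2", "e2"), E = "e2")

# expected within-pair covariance given component variances
twin_pair_cov <- function(model, v, zyg) {
  switch(model,
    ACE = if (zyg == "MZ") v["a2"] + v["c2"] else 0.5 * v["a2"] + v["c2"],
    ADE = if (zyg == "MZ") v["a2"] + v["d2"] else 0.5 * v["a2"] + 0.25 * v["d2"],
    AE = if (zyg == "MZ") v["a2"] else 0.5 * v["a2"],
    CE = v["c2"],
    E = 0 * v["e2"])
}

# negative log-likelihood of the bivariate-normal twin model; params are
# (mu, inv_softplus(component variances)) so components stay positive
twin_nll <- function(par, pairs, model) {
  comps <- twin_model_components[[model]]
  mu <- par[1]
  v <- setNames(softplus(par[-1]), comps)
  vt <- sum(v)
  nll <- 0
  for (zyg in c("MZ", "DZ")) {
    d <- pairs[pairs$zygosity == zyg, ]
    if (nrow(d) == 0) next
    cv <- unname(twin_pair_cov(model, v, zyg))
    det <- vt^2 - cv^2
    if (det <= 0 || vt <= 0) return(1e10)
    d1 <- d$value1 - mu; d2 <- d$value2 - mu
    q <- (vt * (d1^2 + d2^2) - 2 * cv * d1 * d2) / det
    nll <- nll + 0.5 * sum(log(det) + q) + nrow(d) * log(2 * pi)
  }
  nll
}

#' Fit a classical twin variance-components model by maximum likelihood
#'
#' Decomposes the within-pair covariance structure of MZ and DZ twins into
#' additive genetic (A), common environmental (C) or dominance (D), and
#' unique environmental (E) variance under a bivariate normal likelihood
#' with a single free mean and total variance shared across zygosity
#' groups. Expected co-twin covariances: ACE — MZ `a2 + c2`, DZ
#' `a2/2 + c2`; ADE — MZ `a2 + d2`, DZ `a2/2 + d2/4`. Components are kept
#' non-negative by a softplus reparameterization and optimised by
#' quasi-Newton with random restarts.
#'
#' @param pairs Tibble from [twin_pairs()].
#' @param model One of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param min_pairs Minimum pairs per zygosity group (default 10; the E and
#'   CE models only need total pairs).
#' @param n_restarts Random restarts added to the moment-based start.
#' @return Object of class `twin_fit` with proportions `a2`, `c2`, `d2`,
#'   `e2` (summing to 1), `total_variance`, `mean`, `loglik`, `converged`
#'   and `boundary` flags.
#' @export
fit_twin_model <- function(pairs, model = c("ACE", "ADE", "AE", "CE", "E"),
                           min_pairs = 10, n_restarts = 3) {
  model <- match.arg(model)
  n_mz <- sum(pairs$zygosity == "MZ"); n_dz <- sum(pairs$zygosity == "DZ")
  if (model %in% c("ACE", "ADE", "AE")) {
    assert_that(n_mz >= min_pairs && n_dz >= min_pairs,
                sprintf("need at least %d pairs per zygosity", min_pairs))
  } else {
    assert_that(n_mz + n_dz >= min_pairs,
                sprintf("need at least %d pairs", min_pairs))
  }
  comps <- twin_model_components[[model]]
  y <- c(pairs$value1, pairs$value2)
  vtot <- var(y); mu0 <- mean(y)
  rc <- twin_correlations(pairs)
  # moment-based split of the total variance as a starting point
  start_v <- switch(model,
    ACE = c(max(2 * (rc$rmz - rc$rdz), 0.05), max(2 * rc$rdz - rc$rmz, 0.05),
            max(1 - rc$rmz, 0.05)),
    ADE = c(max(4 * rc$rdz - rc$rmz, 0.05), max(2 * rc$rmz - 4 * rc$rdz, 0.05),
            max(1 - rc$rmz, 0.05)),
    AE = c(max(rc$rmz, 0.05), max(1 - rc$rmz, 0.05)),
    CE = c(max(rc$rmz, 0.05), max(1 - rc$rmz, 0.05)),
    E = 1)
  start_v <- start_v / sum(start_v) * vtot
  starts <- list(c(mu0, inv_softplus(start_v)))
  for (r in seq_len(n_restarts)) {
    starts <- c(starts, list(c(mu0, inv_softplus(
      runif(length(comps), 0.05, 1) * vtot))))
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, twin_nll, pairs = pairs, model = model, method = "BFGS",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  assert_that(!is.null(best), "twin model optimisation failed at every start")
  converged <- best$convergence == 0
  if (!converged) rlang::warn("twin model did not converge; estimates returned")
  v <- setNames(softplus(best$par[-1]), comps)
  vt <- sum(v)
  prop <- setNames(numeric(4), c("a2", "c2", "d2", "e2"))
  prop[comps] <- v / vt
  structure(list(model = model, a2 = prop[["a2"]], c2 = prop[["c2"]],
                 d2 = prop[["d2"]], e2 = prop[["e2"]],
                 total_variance = vt, mean = best$par[1],
                 loglik = -best$value, converged = converged,
                 boundary = prop[comps] < 1e-6,
                 n_mz = n_mz, n_dz = n_dz),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("<twin_fit %s: a2=%.3f c2=%.3f d2=%.3f e2=%.3f loglik=%.2f%s>\n",
              x$model, x$a2, x$c2, x$d2, x$e2, x$loglik,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Likelihood-ratio test between nested twin models
#'
#' @param full,reduced Two [fit_twin_model()] fits on the same pairs; the
#'   reduced model's components must be a subset of the full model's.
#' @return List with `statistic` (clipped at 0), `df` and `p` from the
#'   chi-square reference distribution.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  assert_that(inherits(full, "twin_fit") && inherits(reduced, "twin_fit"),
              "inputs must be twin_fit objects")
  cf <- twin_model_components[[full$model]]
  cr <- twin_model_components[[reduced$model]]
  assert_that(all(cr %in% cf) && length(cr) < length(cf),
              sprintf("%s is not nested in %s", reduced$model, full$model))
  assert_that(full$n_mz == reduced$n_mz && full$n_dz == reduced$n_dz,
              "fits are based on different pair sets")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- length(cf) - length(cr)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Per-site twin analysis
#'
#' Runs twin correlations, the Falconer estimate and the ACE, ADE, AE and E
#' models for every site, with likelihood-ratio tests for the A, C and D
#' components.
#'
#' @param meth Sites x samples (residualized) matrix.
#' @param ped Pedigree tibble.
#' @param min_pairs Passed to [fit_twin_model()].
#' @return Tibble, one row per site: correlations, Falconer `h2_twins`, ACE
#'   and ADE estimates, and `p_a`, `p_c`, `p_d` from LRTs (A tested as AE
#'   vs E, C as ACE vs AE, D as ADE vs AE), plus a `status` column.
#' @export
fit_twin_models_sites <- function(meth, ped, min_pairs = 10) {
  check_meth_matrix(meth)
  purrr::map_dfr(rownames(meth), function(sid) {
    vals <- meth[sid, ]
    pr <- twin_pairs(ped, vals)
    out <- tibble(site_id = sid, rmz = NA_real_, rdz = NA_real_,
                  h2_twins = NA_real_, a2 = NA_real_, c2 = NA_real_,
                  e2 = NA_real_, a2_ade = NA_real_, d2 = NA_real_,
                  p_a = NA_real_, p_c = NA_real_, p_d = NA_real_,
                  loglik_ace = NA_real_, status = "failed")
    tryCatch({
      rc <- twin_correlations(pr)
      fh <- falconer_h2(rc)
      ace <- fit_twin_model(pr, "ACE", min_pairs)
      ade <- fit_twin_model(pr, "ADE", min_pairs)
      ae <- fit_twin_model(pr, "AE", min_pairs)
      e <- fit_twin_model(pr, "E", min_pairs)
      out <- tibble(site_id = sid, rmz = rc$rmz, rdz = rc$rdz,
                    h2_twins = fh$h2,
                    a2 = ace$a2, c2 = ace$c2, e2 = ace$e2,
                    a2_ade = ade$a2, d2 = ade$d2,
                    p_a = likelihood_ratio_test(ae, e)$p,
                    p_c = likelihood_ratio_test(ace, ae)$p,
                    p_d = likelihood_ratio_test(ade, ae)$p,
                    loglik_ace = ace$loglik,
                    status = if (ace$converged && ade$converged) "ok"
                             else "not_converged")
      out
    }, error = function(err) out)
  })
}
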