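#' Moderator variables for variance-interaction models
#'
#' Age enters the interaction models z-transformed; sex enters as a 0/1
#' indicator. The z-scoring mean and standard deviation are stored so that
#' heritability can later be evaluated at chosen ages (e.g., 25 and 50) on
#' the same internal scale.
#'
#' @param ages Ages in years.
#' @param mean,sd Centering mean and scaling s.d. in years; default to the
#'   sample's own values.
#' @return Object of class `moderator`.
#' @export
moderator_from_age <- function(ages, mean = NULL, sd = NULL) {
  mean <- mean %||% base::mean(ages)
  sd <- sd %||% stats::sd(ages)
  assert_that(sd > 0, "age standard deviation must be positive")
  structure(list(values = (ages - mean) / sd, kind = "age_z",
                 source_mean = mean, source_sd = sd),
            class = "moderator")
}

#' @rdname moderator_from_age
#' @param sex01 Sex coded 0/1.
#' @export
moderator_from_sex <- function(sex01) {
  assert_that(all(sex01 %in% c(0, 1)), "sex must be coded 0/1")
  structure(list(values = as.numeric(sex01), kind = "sex01",
                 source_mean = NA_real_, source_sd = NA_real_),
            class = "moderator")
}

# convert an age in years to the model's internal moderator scale
age_to_m <- function(mod, age_years) {
  assert_that(inherits(mod, "moderator") && mod$kind == "age_z",
              "need an age moderator")
  (age_years - mod$source_mean) / mod$source_sd
}

# moderated-variance likelihood:
# V_ij = A_ij (sa + bg m_i)(sa + bg m_j) + d_ij (se + be m_i)^2, profiled mean
make_mod_lik <- function(y, A, m, max_block = 20) {
  n <- length(y)
  assert_that(all(dim(A) == n), "GRM dimension mismatch")
  assert_that(length(m) == n, "moderator length mismatch")
  pat <- abs(A) > 1e-12
  blocks <- nonzero_components(pat)
  sizes <- lengths(blocks)
  fast <- max(sizes) <= 2
  if (!fast && max(sizes) > max_block) blocks <- list(seq_len(n))

  if (fast) {
    ones <- unlist(blocks[sizes == 1])
    twos <- blocks[sizes == 2]
    i1 <- vapply(twos, `[`, integer(1), 1)
    i2 <- vapply(twos, `[`, integer(1), 2)
    dat <- list(
      y0 = y[ones], m0 = m[ones], a0 = diag(A)[ones],
      y1 = y[i1], y2 = y[i2], m1 = m[i1], m2 = m[i2],
      a11 = diag(A)[i1], a22 = diag(A)[i2], a12 = A[cbind(i1, i2)])
  } else {
    Ab <- lapply(blocks, function(b) A[b, b, drop = FALSE])
    yb <- lapply(blocks, function(b) y[b])
    mb <- lapply(blocks, function(b) m[b])
  }

  function(par) {
    sa <- par[1]; bg <- par[2]; s_e <- par[3]; be <- par[4]
    gv <- sa + bg * m
    ev <- s_e + be * m
    if (min(abs(ev)) < 1e-8) return(1e10)

    if (fast) {
      nll_acc <- 0; num <- 0; den <- 0
      # singletons
      if (length(dat$y0)) {
        g <- sa + bg * dat$m0; e2 <- (s_e + be * dat$m0)^2
        v <- dat$a0 * g^2 + e2
        if (any(v <= 0)) return(1e10)
        num <- num + sum(dat$y0 / v); den <- den + sum(1 / v)
        ld0 <- sum(log(v))
      } else ld0 <- 0
      # pairs
      g1 <- sa + bg * dat$m1; g2 <- sa + bg * dat$m2
      e1 <- (s_e + be * dat$m1)^2; e2 <- (s_e + be * dat$m2)^2
      v1 <- dat$a11 * g1^2 + e1
      v2 <- dat$a22 * g2^2 + e2
      cv <- dat$a12 * g1 * g2
      det <- v1 * v2 - cv^2
      if (any(det <= 0) || any(v1 <= 0)) return(1e10)
      # V^{-1} 1 and V^{-1} y accumulations for the profiled mean
      num <- num + sum((v2 * dat$y1 - cv * dat$y2 - cv * dat$y1 + v1 * dat$y2) / det)
      den <- den + sum((v1 + v2 - 2 * cv) / det)
      if (den <= 0) return(1e10)
      mu <- num / den
      if (length(dat$y0)) {
        g <- sa + bg * dat$m0; v <- dat$a0 * g^2 + (s_e + be * dat$m0)^2
        nll_acc <- nll_acc + 0.5 * sum((dat$y0 - mu)^2 / v)
      }
      d1 <- dat$y1 - mu; d2 <- dat$y2 - mu
      quad <- (v2 * d1^2 - 2 * cv * d1 * d2 + v1 * d2^2) / det
      nll_acc <- nll_acc + 0.5 * (ld0 + sum(log(det)) + sum(quad)) +
        0.5 * length(y) * log(2 * pi)
      return(nll_acc)
    }

    logdet <- 0; num <- 0; den <- 0
    Vi_list <- vector("list", length(blocks))
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      g <- gv[b]; e <- ev[b]
      Vb <- Ab[[i]] * tcrossprod(g) + diag(e^2, length(b))
      ch <- tryCatch(chol(Vb), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Vi <- chol2inv(ch)
      Vi_list[[i]] <- Vi
      num <- num + sum(Vi %*% yb[[i]])
      den <- den + sum(Vi)
    }
    if (den <= 0) return(1e10)
    mu <- num / den
    quad <- 0
    for (i in seq_along(blocks)) {
      r <- yb[[i]] - mu
      quad <- quad + sum(r * (Vi_list[[i]] %*% r))
    }
    0.5 * (logdet + quad + length(y) * log(2 * pi))
  }
}

#' Fit a variance-moderation (gene-by-environment interaction) model
#'
#' Models the genetic and residual standard deviations as linear functions
#' of a moderator (0/1 sex or z-scored age): the covariance between
#' individuals i and j is
#' \deqn{V_{ij} = A_{ij}(\sigma_a + \beta_g m_i)(\sigma_a + \beta_g m_j) +
#' \delta_{ij}(\sigma_e + \beta_e m_i)^2} with a free intercept, fitted by
#' maximum likelihood. Each interaction coefficient is tested with a Wald
#' chi-square, `(beta / s.e.)^2` on 1 degree of freedom. The joint sign
#' indeterminacy of each (sigma, beta) pair is resolved by returning
#' `sigma_a >= 0` and `sigma_e >= 0`.
#'
#' @param y Standardized site values.
#' @param A [grm()] (typically the thresholded, IBD-like matrix) or matrix.
#' @param m A [moderator_from_age()] / [moderator_from_sex()] object, or a
#'   plain numeric vector.
#' @param n_restarts Extra random starts.
#' @param hess_step Central-difference step for the observed information.
#' @return Object of class `moderation_fit` with `sigma_a`, `beta_g`,
#'   `sigma_e`, `beta_e`, standard errors, Wald statistics `chi2_g`,
#'   `chi2_e` with p-values, `loglik` and a `converged` flag.
#' @export
fit_moderation <- function(y, A, m, n_restarts = 1, hess_step = 1e-4) {
  M <- as_grm_matrix(A)
  mod <- if (inherits(m, "moderator")) m else
    structure(list(values = as.numeric(m), kind = "custom",
                   source_mean = NA_real_, source_sd = NA_real_),
              class = "moderator")
  mv <- mod$values
  assert_that(sd(mv) > 0, "moderator is constant; interaction unidentifiable")
  nll <- make_mod_lik(y, M, mv)

  vy <- var(y)
  starts <- list(c(sqrt(0.3 * vy), 0, sqrt(0.7 * vy), 0))
  for (r in seq_len(n_restarts)) {
    h <- runif(1, 0.05, 0.8)
    starts <- c(starts, list(c(sqrt(h * vy), rnorm(1, 0, 0.05),
                               sqrt((1 - h) * vy), rnorm(1, 0, 0.05))))
  }
  best <- NULL
  for (s in starts) {
    o1 <- optim(s, nll, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-10))
    o <- tryCatch(optim(o1$par, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10)),
                  error = function(e) o1)
    if (o$value > o1$value) o <- o1
    if (is.null(best) || o$value < best$value) best <- o
  }
  converged <- best$value < 1e9
  if (!converged) rlang::warn("moderation model did not converge")

  par <- best$par
  if (par[1] < 0) par[1:2] <- -par[1:2]
  if (par[3] < 0) par[3:4] <- -par[3:4]

  H <- num_hessian(nll, par, h = rep(hess_step, 4))
  se <- rep(NA_real_, 4)
  singular <- FALSE
  Hi <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Hi) || any(diag(Hi)[c(2, 4)] <= 0)) {
    singular <- TRUE
  } else {
    se <- sqrt(pmax(diag(Hi), 0))
  }

  w_g <- if (singular) list(statistic = NA_real_, p = NA_real_) else
    wald_chi2(par[2], se[2])
  w_e <- if (singular) list(statistic = NA_real_, p = NA_real_) else
    wald_chi2(par[4], se[4])

  structure(list(sigma_a = par[1], beta_g = par[2],
                 sigma_e = par[3], beta_e = par[4],
                 se_sigma_a = se[1], se_beta_g = se[2],
                 se_sigma_e = se[3], se_beta_e = se[4],
                 chi2_g = w_g$statistic, p_g = w_g$p,
                 chi2_e = w_e$statistic, p_e = w_e$p,
                 loglik = -best$value, converged = converged && !singular,
                 moderator = mod[c("kind", "source_mean", "source_sd")],
                 n = length(y)),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf(
    "<moderation_fit (%s): sigma_a=%.3f beta_g=%.3f sigma_e=%.3f beta_e=%.3f\n  chi2_g=%.2f (p=%.3g) chi2_e=%.2f (p=%.3g)>\n",
    x$moderator$kind, x$sigma_a, x$beta_g, x$sigma_e, x$beta_e,
    x$chi2_g, x$p_g, x$chi2_e, x$p_e))
  invisible(x)
}

#' Wald chi-square test for one coefficient
#'
#' `chi2 = (beta / se)^2` referred to the chi-square distribution with one
#' degree of freedom.
#'
#' @param beta Estimate.
#' @param se Standard error (must be positive).
#' @return List with `statistic` and `p`.
#' @export
wald_chi2 <- function(beta, se) {
  assert_that(all(se > 0), "standard error must be positive")
  stat <- (beta / se)^2
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Heritability and variance components at a moderator value
#'
#' `Va(m) = (sigma_a + beta_g m)^2`, `Ve(m) = (sigma_e + beta_e m)^2`,
#' `h2(m) = Va / (Va + Ve)`; `h2` is undefined (NA) where both variances
#' vanish.
#'
#' @param fit A [fit_moderation()] object.
#' @param m_value Moderator value(s) on the model's internal scale (0/1 for
#'   sex; z-scored for age — use [age_to_m] semantics via
#'   `variance_profile(..., ages = )` for year inputs).
#' @return `h2_at()` returns heritability value(s); `variance_profile()` a
#'   tibble of class `variance_profile` with `m`, `va`, `ve`, `vtot`, `h2`.
#' @export
h2_at <- function(fit, m_value) {
  va <- (fit$sigma_a + fit$beta_g * m_value)^2
  ve <- (fit$sigma_e + fit$beta_e * m_value)^2
  ifelse(va + ve > 0, va / (va + ve), NA_real_)
}

#' @rdname h2_at
#' @param m_grid Moderator grid on the internal scale.
#' @param ages Optional ages in years (for age-moderator fits); converted
#'   with the stored z-scoring mean and s.d. and used instead of `m_grid`.
#' @export
variance_profile <- function(fit, m_grid = seq(-2, 2, by = 0.1), ages = NULL) {
  if (!is.null(ages)) {
    assert_that(fit$moderator$kind == "age_z",
                "`ages` only applies to age-moderated fits")
    m_grid <- (ages - fit$moderator$source_mean) / fit$moderator$source_sd
  }
  va <- (fit$sigma_a + fit$beta_g * m_grid)^2
  ve <- (fit$sigma_e + fit$beta_e * m_grid)^2
  out <- tibble(m = m_grid,
                age = if (is.null(ages)) NA_real_ else ages,
                va = va, ve = ve, vtot = va + ve,
                h2 = ifelse(va + ve > 0, va / (va + ve), NA_real_))
  class(out) <- c("variance_profile", class(out))
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / n_tests`; with 411,169 methylation sites this gives the
#' genome-wide twin-model threshold 1.2e-7, with 391,227 successfully
#' fitted interaction models 1.3e-7, and with 117 enrichment tests 4.27e-4.
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return Adjusted alpha.
#' @examples
#' multiple_testing_threshold(0.05, 117)
#' @export
multiple_testing_threshold <- function(alpha, n_tests) {
  assert_that(alpha > 0 && alpha < 1, "`alpha` must be in (0, 1)")
  assert_that(n_tests >= 1, "`n_tests` must be at least 1")
  alpha / n_tests
}

#' Moderation fits for every site
#'
#' @param meth Sites x samples standardized matrix.
#' @param A GRM for the genetic term.
#' @param m Moderator object.
#' @param h2_eval Named vector of moderator values at which to report
#'   heritability (defaults: sex 0/1, or ages 25 and 50 for age fits).
#' @param ... Passed to [fit_moderation()].
#' @return Tibble, one row per site.
#' @export
fit_moderation_sites <- function(meth, A, m, h2_eval = NULL, ...) {
  check_meth_matrix(meth)
  if (is.null(h2_eval)) {
    h2_eval <- if (inherits(m, "moderator") && m$kind == "age_z") {
      c(h2_age25 = (25 - m$source_mean) / m$source_sd,
        h2_age50 = (50 - m$source_mean) / m$source_sd)
    } else c(h2_m0 = 0, h2_m1 = 1)
  }
  purrr::map_dfr(rownames(meth), function(sid) {
    fit <- tryCatch(fit_moderation(meth[sid, ], A, m, ...),
                    error = function(e) NULL)
    base <- tibble(site_id = sid, sigma_a = NA_real_, beta_g = NA_real_,
                   sigma_e = NA_real_, beta_e = NA_real_,
                   se_beta_g = NA_real_, se_beta_e = NA_real_,
                   chi2_g = NA_real_, p_g = NA_real_,
                   chi2_e = NA_real_, p_e = NA_real_, status = "failed")
    if (is.null(fit)) {
      h2cols <- setNames(rep(NA_real_, length(h2_eval)), names(h2_eval))
      return(dplyr::bind_cols(base, tibble::as_tibble_row(h2cols)))
    }
    row <- tibble(site_id = sid, sigma_a = fit$sigma_a, beta_g = fit$beta_g,
                  sigma_e = fit$sigma_e, beta_e = fit$beta_e,
                  se_beta_g = fit$se_beta_g, se_beta_e = fit$se_beta_e,
                  chi2_g = fit$chi2_g, p_g = fit$p_g,
                  chi2_e = fit$chi2_e, p_e = fit$p_e,
                  status = if (fit$converged) "ok" else "not_converged")
    h2cols <- setNames(h2_at(fit, unname(h2_eval)), names(h2_eval))
    dplyr::bind_cols(row, tibble::as_tibble_row(h2cols))
  })
}
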