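#' Tidy a twin model fit
#'
#' @param x A `twin_fit` object.
#' @param ... Unused.
#' @return One row per variance component with `term` and `estimate`
#'   (proportion of total variance).
#' @export
tidy.twin_fit <- function(x, ...) {
  comps <- twin_model_components[[x$model]]
  tibble(term = comps,
         estimate = vapply(comps, function(k) x[[k]], numeric(1)))
}

#' @rdname tidy.twin_fit
#' @export
glance.twin_fit <- function(x, ...) {
  tibble(model = x$model, logLik = x$loglik,
         total_variance = x$total_variance, mean = x$mean,
         n_mz = x$n_mz, n_dz = x$n_dz, converged = x$converged)
}

#' Tidy a two-GRM variance-components fit
#'
#' @param x A `two_grm_fit` object.
#' @param ... Unused.
#' @return One row per variance component with estimate and standard error.
#' @export
tidy.two_grm_fit <- function(x, ...) {
  tibble(term = c("sigma2_snp", "sigma2_ped", "sigma2_e"),
         estimate = c(x$sigma2_snp, x$sigma2_ped, x$sigma2_e),
         std.error = c(x$se_snp, x$se_ped, x$se_e))
}

#' @rdname tidy.two_grm_fit
#' @export
glance.two_grm_fit <- function(x, ...) {
  tibble(h2_ibd = x$h2_ibd, h2_snps = x$h2_snps, ratio_snp = x$ratio_snp,
         logLik = x$loglik, n = x$n, converged = x$converged)
}

#' Tidy a variance-moderation fit
#'
#' @param x A `moderation_fit` object.
#' @param ... Unused.
#' @return One row per parameter with estimate, standard error, Wald
#'   statistic and p-value (interaction terms only).
#' @export
tidy.moderation_fit <- function(x, ...) {
  tibble(term = c("sigma_a", "beta_g", "sigma_e", "beta_e"),
         estimate = c(x$sigma_a, x$beta_g, x$sigma_e, x$beta_e),
         std.error = c(x$se_sigma_a, x$se_beta_g, x$se_sigma_e, x$se_beta_e),
         statistic = c(NA, x$chi2_g, NA, x$chi2_e),
         p.value = c(NA, x$p_g, NA, x$p_e))
}

#' @rdname tidy.moderation_fit
#' @export
glance.moderation_fit <- function(x, ...) {
  tibble(moderator = x$moderator$kind, logLik = x$loglik, n = x$n,
         converged = x$converged)
}

#' Plot variance and heritability trajectories over a moderator
#'
#' Draws the additive genetic variance, unique environmental variance,
#' total variance, and heritability of one site against the moderator
#' (e.g., age), the standard way to display variance-moderation fits.
#'
#' @param object A `variance_profile` tibble from [variance_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variance_profile <- function(object, ...) {
  xvar <- if (!all(is.na(object$age))) "age" else "m"
  long <- tidyr::pivot_longer(object, c("va", "ve", "vtot", "h2"),
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, c("va", "ve", "vtot", "h2"),
                          c("additive genetic variance",
                            "unique environmental variance",
                            "total variance", "heritability"))
  ggplot2::ggplot(long, ggplot2::aes(.data[[xvar]], .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = if (xvar == "age") "age (years)" else "moderator",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of heritability estimates across the catalogue
#'
#' @param catalogue Catalogue tibble with `h2_ibd` and optionally
#'   `h2_snps`.
#' @param bins Number of histogram bins.
#' @return A ggplot object overlaying total and SNP heritability.
#' @export
plot_h2_distribution <- function(catalogue, bins = 30) {
  cols <- intersect(c("h2_ibd", "h2_snps"), names(catalogue))
  assert_that(length(cols) > 0, "catalogue has no heritability columns")
  long <- tidyr::pivot_longer(catalogue[, c("site_id", cols)], -"site_id",
                              names_to = "estimate", values_to = "h2")
  ggplot2::ggplot(long, ggplot2::aes(.data$h2, fill = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "heritability", y = "number of sites", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of twin-based versus GRM-based heritability
#'
#' @param equivalence Result of [twin_grm_equivalence_check()].
#' @return A ggplot object with the identity line.
#' @export
plot_twin_grm_equivalence <- function(equivalence) {
  d <- equivalence$per_site
  ggplot2::ggplot(d, ggplot2::aes(.data$h2_twins, .data$h2_ibd)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "twin AE heritability",
                  y = "pedigree-GRM heritability",
                  subtitle = sprintf("r = %.3f", equivalence$correlation)) +
    ggplot2::theme_minimal()
}
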