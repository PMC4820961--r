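#' Methylation beta value from probe intensities
#'
#' Computes the methylation proportion (beta value) from methylated and
#' unmethylated signal intensities with the conventional stabilising offset:
#' \deqn{\beta = M / (M + U + \alpha)}
#' With a positive offset `alpha` the beta value lies in \[0, 1) even when
#' both signals are zero.
#'
#' @param m_signal Methylated signal intensity (non-negative, vectorised).
#' @param u_signal Unmethylated signal intensity (non-negative, vectorised).
#' @param alpha Offset added to the denominator; 100 by default.
#' @return Numeric vector of beta values in `[0, 1)`.
#' @examples
#' beta_from_intensities(1000, 900)  # 0.5
#' @export
beta_from_intensities <- function(m_signal, u_signal, alpha = 100) {
  assert_that(all(alpha > 0), "`alpha` must be positive")
  assert_that(all(m_signal >= 0, na.rm = TRUE) && all(u_signal >= 0, na.rm = TRUE),
              "intensities must be non-negative")
  m_signal / (m_signal + u_signal + alpha)
}

#' Convert between beta and M values
#'
#' The M value is the log2 logistic transform of the methylation proportion,
#' `M = log2(beta / (1 - beta))`; `beta_from_m()` is its exact inverse.
#' Beta values of exactly 0 or 1 (which cannot arise from the offset
#' intensity formula but can occur in synthetic or rounded data) are clamped
#' to `[eps, 1 - eps]` with a warning before transforming.
#'
#' @param beta Methylation proportions in `(0, 1)` (vectorised).
#' @param m M values (vectorised).
#' @param eps Clamping bound for beta values at the endpoints.
#' @return `m_from_beta()` returns M values; `beta_from_m()` returns beta
#'   values in `(0, 1)`.
#' @examples
#' m_from_beta(0.8)        # log2(4) = 2
#' beta_from_m(m_from_beta(0.3))
#' @export
m_from_beta <- function(beta, eps = 1e-6) {
  assert_that(all(beta >= 0 & beta <= 1, na.rm = TRUE),
              "beta values must lie in [0, 1]")
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    rlang::warn("beta values at 0 or 1 clamped before M transform")
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log2(beta / (1 - beta))
}

#' @rdname m_from_beta
#' @export
beta_from_m <- function(m) {
  1 / (1 + 2^(-m))
}
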