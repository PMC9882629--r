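#' Variance-stabilizing transformation for NB counts
#'
#' Closed-form transform for the parametric dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}: with q the normalised count,
#' \deqn{vst(q) = \log_2\!\frac{1 + a_1 + 2 a_0 q +
#'   2\sqrt{a_0 q (1 + a_1 + a_0 q)}}{4 a_0},}
#' the antiderivative of \eqn{1/\sqrt{v(\mu)}} for the NB variance
#' \eqn{v(\mu) = \mu(1+a_1) + a_0\mu^2}, rescaled so that it
#' approaches log2 of the normalised count for large counts. Strictly
#' increasing in the input; variance approximately flat across the
#' mean range. When `a0 <= 0` there is nothing to stabilise against
#' and the function falls back to `log2(q + 1)` with a warning.
#'
#' @param counts gene x sample integer matrix.
#' @param size_factors per-sample positive reals.
#' @param trend_coeffs numeric `c(a0, a1)`, e.g.
#'   `fit_dispersions(...)$trend_coeffs`.
#' @return numeric matrix, same dimensions and dimnames as `counts`.
#' @export
vst_transform <- function(counts, size_factors, trend_coeffs) {
  q <- sweep(counts, 2, size_factors[colnames(counts)], "/")
  a0 <- unname(trend_coeffs[1]); a1 <- unname(trend_coeffs[2])
  if (!is.finite(a0) || a0 <= 0) {
    warnf("trend asymptote a0 <= 0: falling back to log2(q + 1)")
    return(log2(q + 1))
  }
  if (!is.finite(a1) || a1 < 0) a1 <- 0
  log2((1 + a1 + 2 * a0 * q +
          2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
}
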