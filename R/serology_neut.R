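#' Percent neutralization
#'
#' `100 * (virus_only - virus_plus_serum) / virus_only`. Values can be
#' negative (infection enhancement); no clipping is applied here —
#' clipping decisions belong to the ID50 stage.
#'
#' @param virus_only_rlu mean RLU of the virus-only control (> 0).
#' @param virus_plus_serum_rlu RLU of serum wells (vectorised).
#' @return percent neutralization.
#' @export
percent_neutralization <- function(virus_only_rlu, virus_plus_serum_rlu) {
  if (!is.finite(virus_only_rlu) || virus_only_rlu <= 0)
    stopf("virus-only control RLU must be positive")
  100 * (virus_only_rlu - virus_plus_serum_rlu) / virus_only_rlu
}

#' Construct a neutralization curve
#'
#' @param sample_id serum identifier.
#' @param dilutions reciprocal serum dilutions, strictly increasing,
#'   starting at the 1:20 input dilution.
#' @param rlu matrix (dilutions x replicates) or vector of RLU.
#' @param virus_only_rlu replicate RLU of the virus-only control.
#' @param cell_only_rlu replicate RLU of the cell-only control.
#' @return object of class `neut_curve`.
#' @export
neut_curve <- function(sample_id, dilutions, rlu, virus_only_rlu,
                       cell_only_rlu = 0) {
  if (!length(dilutions)) stopf("empty dilution series")
  if (any(diff(dilutions) <= 0))
    stopf("reciprocal dilutions must be strictly increasing")
  if (!is.matrix(rlu)) rlu <- matrix(rlu, nrow = length(dilutions))
  if (nrow(rlu) != length(dilutions))
    stopf("rlu rows must match dilutions")
  if (mean(virus_only_rlu) <= mean(cell_only_rlu))
    stopf("virus-only control must exceed cell-only control")
  structure(list(sample_id = sample_id, dilutions = dilutions, rlu = rlu,
                 virus_only_rlu = virus_only_rlu,
                 cell_only_rlu = cell_only_rlu),
            class = "neut_curve")
}

#' 50% inhibitory dilution (ID50)
#'
#' Percent neutralization is averaged per dilution against the mean
#' virus-only control; the ID50 is the reciprocal dilution at 50%
#' neutralization, estimated by fitting
#' \eqn{pn(d) = 100 / (1 + (d/ID50)^h)} in log-dilution and falling
#' back to linear interpolation in log-dilution between the bracketing
#' pair if the fit fails. Curves that never reach 50% neutralization
#' anywhere in the series are censored at the assay's lower limit of
#' quantification, the 1:20 input dilution.
#'
#' @param curve a `neut_curve` (>= 3 dilutions).
#' @param lloq lower limit of quantification (reciprocal dilution).
#' @param monotone_tol flag curves whose mean percent neutralization
#'   rises by more than this between successive (increasing)
#'   dilutions.
#' @param estimator `"logistic"` (default, with interpolation
#'   fallback) or `"interpolation"` to force the deterministic
#'   log-dilution interpolation.
#' @return list `id50`, `censored`, `method` (`logistic` /
#'   `interpolation` / `censored`), `percent` (per-dilution means),
#'   `qc_flags`.
#' @export
compute_id50 <- function(curve, lloq = 20, monotone_tol = 15,
                         estimator = c("logistic", "interpolation")) {
  estimator <- match.arg(estimator)
  if (!inherits(curve, "neut_curve")) stopf("curve must be a neut_curve")
  d <- curve$dilutions
  if (length(d) < 3) stopf("need at least 3 dilutions")
  v0 <- mean(curve$virus_only_rlu)
  pn <- apply(curve$rlu, 1, function(r) mean(percent_neutralization(v0, r)))
  qc <- character(0)
  if (any(diff(pn) > monotone_tol))
    qc <- c(qc, "non_monotone")
  if (max(pn) < 50) {
    return(list(id50 = lloq, censored = TRUE, method = "censored",
                percent = setNames(pn, d), qc_flags = qc))
  }
  id50 <- NA_real_
  method <- "logistic"
  fit <- if (estimator == "interpolation") NULL else tryCatch({
    start_l <- log(d[which.min(abs(pn - 50))])
    f <- minpack.lm::nlsLM(
      pn ~ 100 / (1 + exp(h * (log(d) - l50))),
      start = list(h = 1.5, l50 = start_l),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(f)
    if (cf[["h"]] <= 0) NULL else exp(cf[["l50"]])
  }, error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit)) {
    id50 <- fit
  } else {
    method <- "interpolation"
    ## last dilution still at/above 50 followed by one below
    idx <- which(pn[-length(pn)] >= 50 & pn[-1] < 50)
    if (length(idx)) {
      i <- idx[length(idx)]
      ld <- log10(d[i]) + (pn[i] - 50) / (pn[i] - pn[i + 1]) *
        (log10(d[i + 1]) - log10(d[i]))
      id50 <- 10^ld
    } else {
      ## 50% reached at the last dilution exactly
      id50 <- d[which.min(abs(pn - 50))]
    }
  }
  if (id50 < lloq) {
    return(list(id50 = lloq, censored = TRUE, method = "censored",
                percent = setNames(pn, d), qc_flags = qc))
  }
  list(id50 = id50, censored = FALSE, method = method,
       percent = setNames(pn, d), qc_flags = qc)
}
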