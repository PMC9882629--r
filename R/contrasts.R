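#' Wald test for a contrast of GLM coefficients
#'
#' For contrast vector c the statistic is
#' \eqn{c'\beta / \sqrt{c' \Sigma c}} with \eqn{\Sigma} the inverse
#' Fisher information of the per-gene fit; two-sided p-values from the
#' standard normal tail, Benjamini-Hochberg FDR across the genes
#' tested in this contrast. Fold changes are reported on the log2
#' scale. Genes that did not converge (or are all-zero) get NA
#' statistics and do not enter the FDR computation.
#'
#' @param fit an `nbglm_fit`.
#' @param contrast numeric contrast vector over the fit's
#'   coefficients.
#' @param label contrast label carried into the result.
#' @return data.frame of class `contrast_result` with columns
#'   `gene_id`, `base_mean`, `log2fc`, `se`, `wald`, `p`, `fdr`.
#' @export
wald_contrast <- function(fit, contrast, label = "contrast") {
  if (!inherits(fit, "nbglm_fit")) stopf("fit must be an nbglm_fit")
  p_coef <- ncol(fit$beta)
  if (length(contrast) != p_coef)
    stopf("contrast length %d != %d coefficients", length(contrast), p_coef)
  if (!is.null(names(contrast)) &&
      !identical(names(contrast), colnames(fit$beta)))
    contrast <- contrast[colnames(fit$beta)]
  G <- nrow(fit$beta)
  est <- drop(fit$beta %*% contrast)      # natural-log scale
  se <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    ch <- fit$chol_info[[g]]
    if (is.null(ch)) next
    v <- backsolve(ch, contrast, transpose = TRUE)
    se[g] <- sqrt(sum(v * v))
  }
  usable <- fit$converged & !fit$degenerate & is.finite(se) & se > 0
  wald <- ifelse(usable, est / se, NA_real_)
  pval <- 2 * pnorm(-abs(wald))
  fdr <- rep(NA_real_, G)
  fdr[usable] <- p.adjust(pval[usable], method = "BH")
  out <- data.frame(gene_id = rownames(fit$beta),
                    base_mean = fit$base_mean,
                    log2fc = est / log(2),
                    se = se / log(2),
                    wald = wald,
                    p = pval,
                    fdr = fdr,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "contrast_label") <- label
  attr(out, "contrast") <- contrast
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Count differentially expressed genes
#'
#' @param result a `contrast_result`.
#' @param alpha FDR threshold (default 0.05).
#' @return integer number of genes with `fdr < alpha`.
#' @export
count_degs <- function(result, alpha = 0.05) {
  sum(result$fdr < alpha, na.rm = TRUE)
}
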