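#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants for sequencing depth and
#' composition. For each gene with strictly positive counts in every
#' sample, the count in sample j is divided by the gene's geometric
#' mean across samples; the size factor of sample j is the median of
#' those ratios.
#'
#' @param counts gene x sample integer matrix.
#' @return named positive numeric vector, one entry per sample.
#' @export
estimate_size_factors <- function(counts) {
  check_counts(counts)
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable))
    stopf(paste("no gene has positive counts in every sample;",
                "median-of-ratios is undefined. Consider filtering",
                "samples or normalising against a pseudo-reference."))
  lc <- log(counts[usable, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- apply(lc, 2L, function(x) exp(median(x - loggeo)))
  setNames(sf, colnames(counts))
}
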