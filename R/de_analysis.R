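#' Differential expression for the longitudinal nested design
#'
#' One call running the whole engine: low-count filter, size factors,
#' dispersion estimation (gene-wise / trend / MAP), negative-binomial
#' GLM fit on the nested design, and Wald contrasts with per-contrast
#' Benjamini-Hochberg FDR. By default both groups are fit jointly (a
#' single model supplies every within-group and between-group
#' contrast); `contrasts` defaults to the standard panel of each
#' post-dose timepoint vs its own dose's baseline plus the
#' between-group comparisons at the shared D7 timepoints.
#'
#' @param counts gene x sample integer matrix.
#' @param sample_info sample metadata (see [nested_design()]).
#' @param contrasts named list of contrast vectors, or NULL for
#'   [standard_contrasts()].
#' @param alpha FDR threshold used for the reported DEG counts.
#' @param min_total_count genes with fewer total counts are excluded
#'   before dispersion fitting (set 0 to disable).
#' @param design optionally a precomputed `nested_design`.
#' @return object of class `de_analysis`: size factors, dispersion
#'   fit, GLM fit, `results` (named list of `contrast_result`),
#'   `deg_counts`, the VST matrix of the retained genes, and the
#'   design.
#' @export
de_analysis <- function(counts, sample_info, contrasts = NULL,
                        alpha = 0.05, min_total_count = 10,
                        design = NULL) {
  check_counts(counts)
  check_sample_info(sample_info, counts)
  si <- sample_info[match(colnames(counts), sample_info$sample_id), ]
  if (is.null(design)) design <- nested_design(si)
  keep <- rowSums(counts) >= min_total_count
  if (!any(keep)) stopf("no gene passes the minimum-count filter")
  cts <- counts[keep, , drop = FALSE]
  sf <- estimate_size_factors(cts)
  disp <- fit_dispersions(cts, sf, design)
  fit <- fit_nbglm(cts, sf, design, disp$map_alpha)
  if (is.null(contrasts)) contrasts <- standard_contrasts(design)
  results <- lapply(names(contrasts), function(nm)
    wald_contrast(fit, contrasts[[nm]], label = nm))
  names(results) <- names(contrasts)
  structure(list(size_factors = sf,
                 dispersion_fit = disp,
                 fit = fit,
                 results = results,
                 deg_counts = vapply(results, count_degs, 0L, alpha = alpha),
                 vst = vst_transform(cts, sf, disp$trend_coeffs),
                 design = design,
                 alpha = alpha,
                 genes_kept = rownames(cts)),
            class = "de_analysis")
}

#' @export
print.de_analysis <- function(x, ...) {
  cat(sprintf("de_analysis: %d genes, %d samples, %d contrasts (FDR < %.2g)\n",
              length(x$genes_kept), ncol(x$vst), length(x$results), x$alpha))
  for (nm in names(x$deg_counts))
    cat(sprintf("  %-24s %5d DEGs\n", nm, x$deg_counts[[nm]]))
  invisible(x)
}

#' Write per-contrast DE results and a run manifest
#'
#' @param de a `de_analysis`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_de_results <- function(de, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(de$results)) {
    fn <- file.path(dir, paste0("contrast_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv"))
    write.csv(de$results[[nm]], fn, row.names = FALSE)
    paths <- c(paths, fn)
  }
  manifest <- list(
    design_coefficients = de$design$coef_names,
    group_reference = de$design$group_ref,
    timepoint_reference = de$design$timepoint_ref,
    alpha = de$alpha,
    genes_tested = length(de$genes_kept),
    converged = sum(de$fit$converged),
    dispersion_trend = as.list(de$dispersion_fit$trend_coeffs),
    deg_counts = as.list(de$deg_counts))
  mf <- file.path(dir, "de_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mf))
}
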