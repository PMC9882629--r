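#' Sign-fixed module eigengenes
#'
#' For each gene set, the eigengene is the first principal component
#' of the set's member rows of the VST matrix across the samples of
#' one dose window, computed on per-gene centered values without
#' variance scaling. The sign is fixed in three steps so that higher
#' member-gene expression maps to a positive score: (1) compute the
#' per-sample median expression across the member genes, (2) compute
#' the Pearson correlation between eigengene and median profile
#' across samples, (3) multiply the eigengene by -1 if that
#' correlation is negative (an exactly zero correlation keeps the
#' sign and raises a tie flag). Dose windows (all V1 samples; all V2
#' samples) are computed independently and their scores are never
#' compared across windows. Single-member sets fall back to the
#' centered gene itself, sign rule still applied.
#'
#' @param vst_matrix gene x sample matrix of variance-stabilised
#'   values.
#' @param sets a [gene_set_collection()].
#' @param sample_window character vector of sample ids forming the
#'   window (>= 3).
#' @param min_members sets with fewer members present are skipped.
#' @return object of class `eigengene_matrix`: `scores` (sets x
#'   samples), `explained_variance`, `tie_flag`, `n_members`,
#'   `skipped`.
#' @export
compute_eigengenes <- function(vst_matrix, sets, sample_window,
                               min_members = 2) {
  absent <- setdiff(sample_window, colnames(vst_matrix))
  if (length(absent))
    stopf("window samples not in matrix: %s", paste(head(absent, 3), collapse = ", "))
  if (length(sample_window) < 3) stopf("need >= 3 samples in the window")
  ids <- names(sets$sets)
  scores <- matrix(NA_real_, length(ids), length(sample_window),
                   dimnames = list(ids, sample_window))
  expl <- setNames(rep(NA_real_, length(ids)), ids)
  tie <- setNames(rep(FALSE, length(ids)), ids)
  nm <- setNames(integer(length(ids)), ids)
  skipped <- character(0)
  for (id in ids) {
    members <- intersect(sets$sets[[id]], rownames(vst_matrix))
    nm[id] <- length(members)
    if (length(members) < 1 ||
        (length(members) < min_members && length(members) != 1)) {
      skipped <- c(skipped, id)
      next
    }
    M <- vst_matrix[members, sample_window, drop = FALSE]
    med_profile <- apply(M, 2, median)
    Mc <- M - rowMeans(M)
    if (nrow(Mc) == 1) {
      eig <- drop(Mc)
      expl[id] <- 1
    } else {
      sv <- svd(Mc)
      eig <- sv$v[, 1] * sv$d[1]
      expl[id] <- sv$d[1]^2 / sum(sv$d^2)
    }
    r <- suppressWarnings(cor(eig, med_profile))
    if (is.na(r)) { r <- 0 }
    if (r < 0) eig <- -eig
    if (r == 0) tie[id] <- TRUE
    scores[id, ] <- eig
  }
  structure(list(scores = scores[setdiff(ids, skipped), , drop = FALSE],
                 explained_variance = expl,
                 tie_flag = tie,
                 n_members = nm,
                 skipped = skipped,
                 window = sample_window),
            class = "eigengene_matrix")
}

#' @export
print.eigengene_matrix <- function(x, ...) {
  cat(sprintf("eigengene_matrix: %d modules x %d samples (%d skipped)\n",
              nrow(x$scores), ncol(x$scores), length(x$skipped)))
  invisible(x)
}

#' Per-subject eigengene changes
#'
#' Post-vaccination score minus pre-vaccination score for each subject
#' and module, using the sample at each of the two time points;
#' subjects missing either sample are excluded and listed.
#'
#' @param eigengenes an `eigengene_matrix`.
#' @param sample_info sample metadata mapping sample to subject and
#'   timepoint.
#' @param pre_timepoint,post_timepoint timepoint labels.
#' @return list `delta` (subjects x modules matrix), `excluded`
#'   (subject ids missing a timepoint).
#' @export
delta_eigengene <- function(eigengenes, sample_info, pre_timepoint,
                            post_timepoint) {
  si <- sample_info[sample_info$sample_id %in% colnames(eigengenes$scores), ]
  pre <- si[si$timepoint == pre_timepoint, ]
  post <- si[si$timepoint == post_timepoint, ]
  subjects <- unique(si$subject_id)
  have <- subjects[subjects %in% pre$subject_id &
                     subjects %in% post$subject_id]
  excluded <- setdiff(subjects, have)
  delta <- vapply(have, function(s) {
    eigengenes$scores[, post$sample_id[match(s, post$subject_id)]] -
      eigengenes$scores[, pre$sample_id[match(s, pre$subject_id)]]
  }, numeric(nrow(eigengenes$scores)))
  if (is.null(dim(delta)))
    delta <- matrix(delta, nrow = nrow(eigengenes$scores),
                    dimnames = list(rownames(eigengenes$scores), have))
  delta <- t(delta)
  rownames(delta) <- have
  colnames(delta) <- rownames(eigengenes$scores)
  list(delta = delta, excluded = excluded,
       pre = pre_timepoint, post = post_timepoint)
}

#' Per-module titer models on eigengene changes
#'
#' One linear model per enriched module: log titer ~ eigengene change
#' + SARS-CoV-2 history, with Benjamini-Hochberg FDR across the
#' supplied enriched list only.
#'
#' @param deltas subjects x modules matrix (e.g.
#'   `delta_eigengene(...)$delta`).
#' @param log_titer named per-subject log titer outcome.
#' @param covid_history named per-subject logical.
#' @param enriched_ids module ids to model (the timepoint's enriched
#'   sets); defaults to all columns.
#' @return data.frame `set_id`, `slope`, `se`, `t`, `p`, `fdr`, `n`,
#'   plus `skipped` attribute for modules with too few subjects.
#' @export
btm_titer_models <- function(deltas, log_titer, covid_history,
                             enriched_ids = NULL) {
  enriched_ids <- enriched_ids %||% colnames(deltas)
  missing_ids <- setdiff(enriched_ids, colnames(deltas))
  if (length(missing_ids))
    stopf("modules not in delta matrix: %s", paste(missing_ids, collapse = ", "))
  rows <- list()
  skipped <- character(0)
  for (id in enriched_ids) {
    df <- data.frame(y = log_titer[rownames(deltas)],
                     d = deltas[, id],
                     h = as.logical(covid_history[rownames(deltas)]))
    df <- df[complete.cases(df), ]
    if (nrow(df) <= 3) { skipped <- c(skipped, id); next }
    fit <- if (length(unique(df$h)) > 1) lm(y ~ d + h, df) else lm(y ~ d, df)
    sm <- summary(fit)$coefficients
    rows[[length(rows) + 1]] <- data.frame(
      set_id = id, slope = sm["d", 1], se = sm["d", 2],
      t = sm["d", 3], p = sm["d", 4], n = nrow(df),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(set_id = character(0), slope = numeric(0), se = numeric(0),
               t = numeric(0), p = numeric(0), n = integer(0))
  if (nrow(out)) out$fdr <- p.adjust(out$p, method = "BH")
  else out$fdr <- numeric(0)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out[, c("set_id", "slope", "se", "t", "p", "fdr", "n")]
}
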