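#' Model matrix for the nested longitudinal design
#'
#' Encodes group-specific condition effects with individual subjects
#' nested within groups: columns for the intercept, group, a
#' group:subject-within-group term (absorbing per-subject baselines),
#' and group:timepoint interactions carrying the per-group condition
#' effects. Reference levels are group = HC (configurable) and the
#' first timepoint of each group (V1D0 in the standard layout).
#' Columns for group/subject or group/timepoint combinations that do
#' not occur (the two cohorts are sampled on different early days) are
#' all-zero after expansion and are dropped, as are any remaining
#' linearly dependent columns, so the returned matrix is full rank.
#'
#' @param sample_info data.frame with `sample_id`, `group`,
#'   `subject_id`, `timepoint`.
#' @param group_ref reference group level.
#' @param timepoint_ref reference timepoint (default: first level in
#'   `timepoint_levels`).
#' @param timepoint_levels ordering of timepoint labels; defaults to
#'   the order of appearance.
#' @return object of class `nested_design`: list with the model
#'   `matrix` (samples x coefficients), `coef_names`, and bookkeeping
#'   needed to build contrast vectors.
#' @export
nested_design <- function(sample_info, group_ref = "HC",
                          timepoint_ref = NULL, timepoint_levels = NULL) {
  check_sample_info(sample_info)
  si <- sample_info
  glev <- unique(as.character(si$group))
  if (!group_ref %in% glev) group_ref <- glev[1L]
  glev <- c(group_ref, setdiff(glev, group_ref))
  si$group <- factor(as.character(si$group), levels = glev)

  tlev <- timepoint_levels %||% unique(as.character(si$timepoint))
  timepoint_ref <- timepoint_ref %||% tlev[1L]
  tlev <- c(timepoint_ref, setdiff(tlev, timepoint_ref))
  si$timepoint <- factor(as.character(si$timepoint), levels = tlev)

  ## within-group subject index (the nesting device: the same small
  ## integers recur in both groups but only combine with their own
  ## group's indicator)
  idx <- integer(nrow(si))
  for (g in glev) {
    in_g <- si$group == g
    subj <- as.character(si$subject_id[in_g])
    idx[in_g] <- match(subj, unique(subj))
  }
  si$subject_n <- factor(idx)

  mm <- model.matrix(~ group + group:subject_n + group:timepoint, data = si)
  ## drop all-zero columns (non-occurring combinations), then any
  ## remaining aliased columns by QR
  mm <- mm[, colSums(abs(mm)) > 0, drop = FALSE]
  qr_mm <- qr(mm)
  aliased <- character(0)
  if (qr_mm$rank < ncol(mm)) {
    keep <- qr_mm$pivot[seq_len(qr_mm$rank)]
    aliased <- colnames(mm)[-keep]
    mm <- mm[, sort(keep), drop = FALSE]
  }
  rownames(mm) <- si$sample_id
  structure(list(matrix = mm,
                 coef_names = colnames(mm),
                 group_levels = glev,
                 timepoint_levels = tlev,
                 group_ref = group_ref,
                 timepoint_ref = timepoint_ref,
                 aliased = aliased,
                 sample_info = si),
            class = "nested_design")
}

#' @export
print.nested_design <- function(x, ...) {
  cat(sprintf("nested_design: %d samples x %d coefficients (groups: %s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$group_levels, collapse = ", ")))
  invisible(x)
}

coef_index <- function(design, name) {
  i <- match(name, design$coef_names)
  if (is.na(i)) stopf("coefficient '%s' not in design", name)
  i
}

tp_coef_name <- function(design, group, timepoint) {
  sprintf("group%s:timepoint%s", group, timepoint)
}

#' Contrast vectors for the nested design
#'
#' `timepoint_contrast()` builds the within-group contrast of
#' `timepoint` vs `ref_timepoint` for one group (e.g. HD V2D7 vs
#' V2D0), as a difference of group:timepoint coefficients; the global
#' reference timepoint contributes no column. `group_contrast()`
#' builds the between-group interaction contrast at one shared
#' timepoint (HD vs HC change from baseline at, say, V2D7), which is
#' the difference of the two groups' timepoint coefficients.
#'
#' @param design a `nested_design`.
#' @param group group level the contrast refers to.
#' @param timepoint,ref_timepoint timepoint labels.
#' @return numeric contrast vector of length `ncol(design$matrix)`.
#' @export
timepoint_contrast <- function(design, group, timepoint, ref_timepoint) {
  cvec <- numeric(ncol(design$matrix))
  names(cvec) <- design$coef_names
  if (timepoint != design$timepoint_ref)
    cvec[coef_index(design, tp_coef_name(design, group, timepoint))] <- 1
  if (ref_timepoint != design$timepoint_ref)
    cvec[coef_index(design, tp_coef_name(design, group, ref_timepoint))] <- -1
  if (all(cvec == 0)) stopf("contrast is identically zero")
  cvec
}

#' @rdname timepoint_contrast
#' @param group1,group2 the two groups compared (`group1` minus
#'   `group2`).
#' @export
group_contrast <- function(design, timepoint, group1, group2) {
  cvec <- numeric(ncol(design$matrix))
  names(cvec) <- design$coef_names
  cvec[coef_index(design, tp_coef_name(design, group1, timepoint))] <- 1
  cvec[coef_index(design, tp_coef_name(design, group2, timepoint))] <- -1
  cvec
}

#' The standard per-group contrast panel
#'
#' For each group, each post-dose timepoint is contrasted against that
#' dose's own baseline: V1-day labels against V1D0 and V2-day labels
#' against V2D0 (both extracted from the single joint fit). Labels are
#' `"<group> <tp> vs <baseline>"`.
#'
#' @param design a `nested_design`.
#' @return named list of contrast vectors.
#' @export
standard_contrasts <- function(design) {
  out <- list()
  si <- design$sample_info
  for (g in design$group_levels) {
    tps <- as.character(unique(si$timepoint[si$group == g]))
    tps <- design$timepoint_levels[design$timepoint_levels %in% tps]
    for (tp in tps) {
      dose <- substr(tp, 1, 2)
      base <- paste0(dose, "D0")
      if (tp == base || !base %in% tps) next
      lab <- sprintf("%s %s vs %s", g, tp, base)
      out[[lab]] <- timepoint_contrast(design, g, tp, base)
    }
  }
  ## between-group comparisons at the shared D7 timepoints
  if (length(design$group_levels) == 2) {
    g1 <- design$group_levels[2]; g2 <- design$group_levels[1]
    shared <- intersect(
      as.character(unique(si$timepoint[si$group == g1])),
      as.character(unique(si$timepoint[si$group == g2])))
    for (tp in intersect(c("V1D7", "V2D7"), shared)) {
      lab <- sprintf("%s vs %s %s", g1, g2, tp)
      out[[lab]] <- group_contrast(design, tp, g1, g2)
    }
  }
  out
}
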