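#' Kruskal-Wallis test of titer against time, per group
#'
#' Rank-based H with tie correction (chi-square reference, k-1 df),
#' applied separately within each subject group to the titer values
#' across time points. Degenerate all-tied input yields H = 0, p = 1
#' with a warning.
#'
#' @param values numeric titer values.
#' @param timepoint factor/character of the same length.
#' @return list `H`, `df`, `p`.
#' @export
kruskal_titers <- function(values, timepoint) {
  ok <- is.finite(values) & !is.na(timepoint)
  values <- values[ok]; timepoint <- factor(timepoint[ok])
  if (nlevels(timepoint) < 2 || any(table(timepoint) < 2))
    stopf("need >= 2 time points with >= 2 observations each")
  if (length(unique(values)) == 1L) {
    warnf("all values tied; H = 0, p = 1")
    return(list(H = 0, df = nlevels(timepoint) - 1L, p = 1))
  }
  kt <- kruskal.test(values, timepoint)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Pairwise Wilcoxon rank-sum tests with FDR across pairs
#'
#' Two-sided unpaired rank-sum tests for each requested pair of time
#' points, exact enumeration when the combined sample is small (<= 12)
#' and tie-free, otherwise the normal approximation with tie and
#' continuity correction; Benjamini-Hochberg correction across the
#' pairs. A paired signed-rank variant is available behind
#' `paired = TRUE` (off by default).
#'
#' @param values numeric titer values.
#' @param timepoint time point label per value.
#' @param pairs list of 2-vectors of time point labels; defaults to
#'   all pairs.
#' @param subject_id needed only when `paired = TRUE`.
#' @param paired use the signed-rank test on within-subject pairs.
#' @return data.frame: `pair`, `W`, `p`, `fdr`, `n1`, `n2`.
#' @export
pairwise_wilcoxon_fdr <- function(values, timepoint, pairs = NULL,
                                  subject_id = NULL, paired = FALSE) {
  timepoint <- as.character(timepoint)
  tps <- unique(timepoint)
  if (is.null(pairs))
    pairs <- combn(tps, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    x <- values[timepoint == pr[1]]
    y <- values[timepoint == pr[2]]
    if (paired) {
      if (is.null(subject_id)) stopf("paired tests need subject_id")
      sx <- subject_id[timepoint == pr[1]]
      sy <- subject_id[timepoint == pr[2]]
      common <- intersect(sx[is.finite(x)], sy[is.finite(y)])
      x0 <- x[match(common, sx)]; y0 <- y[match(common, sy)]
      wt <- wilcox.test(x0, y0, paired = TRUE, exact = FALSE, correct = TRUE)
      return(data.frame(pair = paste(pr, collapse = " vs "),
                        W = unname(wt$statistic), p = wt$p.value,
                        n1 = length(x0), n2 = length(y0)))
    }
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2)
      stopf("pair %s vs %s has fewer than 2 observations per side",
            pr[1], pr[2])
    ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- (length(x) + length(y) <= 12) && !ties
    wt <- wilcox.test(x, y, alternative = "two.sided",
                      exact = use_exact, correct = TRUE)
    data.frame(pair = paste(pr, collapse = " vs "),
               W = unname(wt$statistic), p = wt$p.value,
               n1 = length(x), n2 = length(y))
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out[, c("pair", "W", "p", "fdr", "n1", "n2")]
}

#' Linear model of a (log) antibody outcome
#'
#' Ordinary least squares with reference coding: group reference HC,
#' gender reference male, race reference = most frequent category.
#' Rank deficiency is an error naming the aliased terms.
#'
#' @param data data.frame holding outcome and predictors.
#' @param outcome outcome column name (already log-transformed by the
#'   caller where appropriate).
#' @param predictors character vector of predictor column names.
#' @return list with `coefficients` data.frame (`term`, `estimate`,
#'   `se`, `t`, `p`), `residual_sd`, `n`, `r_squared`, and the `lm`
#'   fit.
#' @export
titer_linear_model <- function(data, outcome, predictors) {
  df <- data[, c(outcome, predictors), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  if (!nrow(df)) stopf("no complete cases")
  for (p in predictors) {
    v <- df[[p]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      ref <- if (p == "group" && "HC" %in% v) "HC"
        else if (p == "gender" && "male" %in% v) "male"
        else names(sort(table(v), decreasing = TRUE))[1]
      df[[p]] <- factor(v, levels = c(ref, setdiff(unique(v), ref)))
    }
    if (length(unique(df[[p]])) < 2)
      stopf("predictor '%s' is constant (aliased)", p)
  }
  if (nrow(df) <= length(predictors) + 1)
    stopf("need more observations than parameters")
  fml <- as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stopf("rank-deficient model; aliased terms: %s", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  list(coefficients = co, residual_sd = sm$sigma, n = nrow(df),
       r_squared = sm$r.squared, fit = fit)
}

#' Demographics comparison table
#'
#' A two-group summary in the style of a clinical Table 1: categorical
#' rows compared by two-sided Fisher's exact test on the 2x2 table of
#' counts vs group (the two-sided p being the total probability of
#' tables no more likely than the observed one), continuous rows by
#' Welch's t-test; rendered as counts or mean (sd) per group.
#'
#' @param cohort data.frame with a `group` column, logical/0-1 columns
#'   for categorical rows and numeric columns for continuous rows.
#' @param categorical,continuous column names; defaults: logical
#'   columns are categorical, numeric (non-binary) are continuous.
#' @return data.frame `variable`, `type`, one summary column per
#'   group, `p`.
#' @export
demographics_table <- function(cohort, categorical = NULL, continuous = NULL) {
  glev <- unique(as.character(cohort$group))
  if (length(glev) != 2) stopf("exactly two groups required")
  cols <- setdiff(names(cohort), c("group", "subject_id"))
  is_cat <- vapply(cols, function(cl) {
    v <- cohort[[cl]]
    is.logical(v) || all(v %in% c(0, 1, NA))
  }, TRUE)
  categorical <- categorical %||% cols[is_cat]
  continuous <- continuous %||% cols[!is_cat & vapply(cols, function(cl)
    is.numeric(cohort[[cl]]), TRUE)]
  rows <- list()
  for (cl in categorical) {
    v <- as.logical(cohort[[cl]])
    tab <- vapply(glev, function(g) {
      c(sum(v[cohort$group == g], na.rm = TRUE),
        sum(!v[cohort$group == g], na.rm = TRUE))
    }, numeric(2))
    p <- fisher.test(tab)$p.value
    rows[[length(rows) + 1]] <- data.frame(
      variable = cl, type = "categorical",
      g1 = sprintf("%d/%d", tab[1, 1], sum(tab[, 1])),
      g2 = sprintf("%d/%d", tab[1, 2], sum(tab[, 2])),
      p = p, stringsAsFactors = FALSE)
  }
  for (cl in continuous) {
    v <- cohort[[cl]]
    x <- v[cohort$group == glev[1]]; y <- v[cohort$group == glev[2]]
    p <- t.test(x, y)$p.value
    rows[[length(rows) + 1]] <- data.frame(
      variable = cl, type = "continuous",
      g1 = sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE)),
      g2 = sprintf("%.1f (%.1f)", mean(y, na.rm = TRUE), sd(y, na.rm = TRUE)),
      p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "g1"] <- glev[1]
  names(out)[names(out) == "g2"] <- glev[2]
  out
}
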