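#' Ferritin risk band
#'
#' Serum ferritin 200-1200 ng/mL (bounds inclusive) is the low-risk
#' band associated with lowest all-cause mortality on maintenance
#' dialysis; values below 200 (iron deficiency) or above 1200
#' (hyper-inflammation) are high risk.
#'
#' @param value ferritin in ng/mL (vectorised, >= 0).
#' @return character vector `"low"` / `"high"`.
#' @export
ferritin_risk <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stopf("ferritin cannot be negative")
  ifelse(is.na(value), NA_character_,
         ifelse(value >= 200 & value <= 1200, "low", "high"))
}

#' Baseline clinical values as pre-vaccination medians
#'
#' The baseline per subject and analyte is the median of the (up to
#' three) monthly pre-vaccination values, with the number of values
#' used recorded; ferritin additionally gets its risk band.
#'
#' @param labs long data.frame with `subject_id`, `analyte`, `phase`
#'   (`pre` rows are used), `value`.
#' @return data.frame `subject_id`, `analyte`, `baseline`, `n_values`,
#'   `ferritin_risk` (NA for other analytes).
#' @export
baseline_clinical <- function(labs) {
  pre <- labs[labs$phase == "pre" & is.finite(labs$value), ]
  if (!nrow(pre)) stopf("no pre-vaccination lab values")
  agg <- aggregate(value ~ subject_id + analyte, pre, median)
  cnt <- aggregate(value ~ subject_id + analyte, pre, length)
  out <- merge(agg, cnt, by = c("subject_id", "analyte"),
               suffixes = c("", ".n"))
  names(out) <- c("subject_id", "analyte", "baseline", "n_values")
  out$ferritin_risk <- ifelse(out$analyte == "ferritin",
                              ferritin_risk(out$baseline), NA_character_)
  out[order(out$subject_id, out$analyte), ]
}

#' Post-vaccination log-fold changes of clinical labs
#'
#' Natural-log fold change of the first post-dose measurement from
#' the pre-vaccination baseline median, carrying the day of
#' collection. Non-positive values cannot enter a log ratio and are
#' rejected.
#'
#' @param labs long data.frame as in [baseline_clinical()], with
#'   `post_v1` rows holding `days_after_vaccination`.
#' @return data.frame `subject_id`, `analyte`, `baseline`, `post`,
#'   `lfc`, `days_after_vaccination`.
#' @export
lab_lfc <- function(labs) {
  base <- baseline_clinical(labs)
  post <- labs[labs$phase == "post_v1" & is.finite(labs$value), ]
  m <- merge(base, post[, c("subject_id", "analyte", "value",
                            "days_after_vaccination")],
             by = c("subject_id", "analyte"))
  if (any(m$baseline <= 0 | m$value <= 0))
    stopf("non-positive lab values cannot enter a log-fold change")
  data.frame(subject_id = m$subject_id, analyte = m$analyte,
             baseline = m$baseline, post = m$value,
             lfc = log(m$value / m$baseline),
             days_after_vaccination = m$days_after_vaccination,
             stringsAsFactors = FALSE)
}

#' Baseline clinical predictors of antibody response
#'
#' One linear model per analyte and outcome: log titer ~ analyte
#' baseline + SARS-CoV-2 history. Ferritin enters as its binary risk
#' band (low vs high); the other analytes as continuous baselines.
#' Subjects missing an outcome are excluded from that outcome's model
#' only. Analytes whose predictor is constant are skipped.
#'
#' @param baselines output of [baseline_clinical()].
#' @param outcomes named list of per-subject named log-titer vectors
#'   (e.g. `list(v2d7 = ..., m6 = ...)`).
#' @param covid_history named per-subject logical.
#' @param analytes which analytes to model.
#' @return data.frame `analyte`, `outcome`, `term`, `estimate`, `se`,
#'   `t`, `p`, `n`.
#' @export
baseline_clinical_models <- function(baselines, outcomes, covid_history,
                                     analytes = c("urr", "ferritin",
                                                  "transferrin_sat",
                                                  "hgb", "wbc")) {
  rows <- list()
  for (an in analytes) {
    b <- baselines[baselines$analyte == an, ]
    pred <- if (an == "ferritin") {
      factor(b$ferritin_risk, levels = c("high", "low"))
    } else b$baseline
    names(pred) <- b$subject_id
    for (oc in names(outcomes)) {
      y <- outcomes[[oc]]
      common <- intersect(names(y)[is.finite(y)], b$subject_id)
      if (length(common) < 5) next
      df <- data.frame(y = y[common], x = pred[common],
                       h = as.logical(covid_history[common]))
      df <- df[complete.cases(df), ]
      if (length(unique(df$x)) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          analyte = an, outcome = oc, term = "x", estimate = NA_real_,
          se = NA_real_, t = NA_real_, p = NA_real_, n = nrow(df),
          skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      fit <- if (length(unique(df$h)) > 1) lm(y ~ x + h, df) else lm(y ~ x, df)
      sm <- summary(fit)$coefficients
      xterm <- grep("^x", rownames(sm), value = TRUE)[1]
      rows[[length(rows) + 1]] <- data.frame(
        analyte = an, outcome = oc, term = xterm,
        estimate = sm[xterm, 1], se = sm[xterm, 2],
        t = sm[xterm, 3], p = sm[xterm, 4], n = nrow(df),
        skipped = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lab log-fold-change predictors of antibody response
#'
#' One model per analyte and outcome on the post-V1 log-fold change,
#' with configurable covariates (default: SARS-CoV-2 history and the
#' day the post-dose labs were collected). A lymphocyte variant with
#' different covariates is just a different `analytes` / `covariates`
#' call.
#'
#' @param lfcs output of [lab_lfc()].
#' @param outcomes named list of per-subject named log-titer vectors.
#' @param covariates data.frame indexed by `subject_id` with any of
#'   `covid_history`, `baseline_log_titer`; days of collection come
#'   from `lfcs`.
#' @param analytes analytes to model.
#' @param covariate_terms which covariates to adjust for.
#' @return data.frame like [baseline_clinical_models()].
#' @export
lfc_clinical_models <- function(lfcs, outcomes, covariates,
                                analytes = c("ferritin", "transferrin_sat",
                                             "wbc"),
                                covariate_terms = c("covid_history",
                                                    "days_after_vaccination")) {
  rows <- list()
  for (an in analytes) {
    l <- lfcs[lfcs$analyte == an, ]
    for (oc in names(outcomes)) {
      y <- outcomes[[oc]]
      common <- intersect(names(y)[is.finite(y)], l$subject_id)
      if (length(common) < 5) next
      li <- l[match(common, l$subject_id), ]
      df <- data.frame(y = y[common], x = li$lfc)
      if ("covid_history" %in% covariate_terms)
        df$h <- as.logical(covariates[common, "covid_history"])
      if ("days_after_vaccination" %in% covariate_terms)
        df$days <- li$days_after_vaccination
      if ("baseline_log_titer" %in% covariate_terms)
        df$y0 <- covariates[common, "baseline_log_titer"]
      df <- df[complete.cases(df), ]
      if (length(unique(df$x)) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          analyte = an, outcome = oc, term = "x", estimate = NA_real_,
          se = NA_real_, t = NA_real_, p = NA_real_, n = nrow(df),
          skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      keep <- vapply(df, function(v) length(unique(v)) > 1, TRUE)
      keep["y"] <- TRUE
      fit <- lm(y ~ ., df[, keep, drop = FALSE])
      sm <- summary(fit)$coefficients
      rows[[length(rows) + 1]] <- data.frame(
        analyte = an, outcome = oc, term = "x",
        estimate = sm["x", 1], se = sm["x", 2],
        t = sm["x", 3], p = sm["x", 4], n = nrow(df),
        skipped = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
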