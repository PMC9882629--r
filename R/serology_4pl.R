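#' Four-parameter logistic standard curves
#'
#' The ELISA calibration model is
#' \deqn{y = d + \frac{a - d}{1 + (x/c)^b}}
#' with lower asymptote `a` (OD at zero analyte), upper asymptote `d`,
#' inflection concentration `c` (units/mL) and slope `b`. `fourpl()`
#' evaluates the curve; `fit_4pl()` estimates the parameters from a
#' standard series by nonlinear least squares with multi-start
#' initialisation from data quantiles.
#'
#' @param x concentrations (units/mL).
#' @param a,b,c,d curve parameters (`d > a`, `c > 0`).
#' @return `fourpl()`: predicted OD. `fit_4pl()`: object of class
#'   `fourpl_fit` with `a`, `b`, `c`, `d`, `residual_sd`, `converged`.
#' @export
fourpl <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)

#' @rdname fourpl
#' @param concentrations standard concentrations (>= 5 distinct,
#'   spanning the inflection).
#' @param responses measured OD at those concentrations.
#' @export
fit_4pl <- function(concentrations, responses) {
  ok <- is.finite(concentrations) & is.finite(responses) & concentrations > 0
  x <- concentrations[ok]; y <- responses[ok]
  if (length(unique(x)) < 5)
    stopf("need at least 5 distinct positive concentrations")
  rng <- diff(range(y))
  ## a ladder sitting on one asymptote produces a nearly flat response;
  ## a usable standard curve must traverse a substantial OD range
  if (rng < 0.5)
    stopf("standard series does not span the inflection (response range %.3g OD)",
          rng)

  a0 <- min(y) - 0.01 * rng
  d0 <- max(y) + 0.01 * rng
  ## slope/EC50 starts from the linearised logit
  fr <- pmin(pmax((y - a0) / (d0 - a0), 1e-4), 1 - 1e-4)
  lf <- qlogis(fr)
  sl <- coef(lm(lf ~ log(x)))
  b0 <- unname(sl[2])
  c0 <- exp(-unname(sl[1]) / b0)
  starts <- list(
    c(a = a0, b = b0, c = c0, d = d0),
    c(a = a0, b = 1, c = exp(mean(log(x))), d = d0),
    c(a = a0, b = 2, c = unname(quantile(x, 0.5)), d = d0))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b),
                        start = as.list(s),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stopf("4PL fit failed from every start")
  cf <- coef(best$fit)
  if (cf["d"] < cf["a"]) { # enforce d > a by swapping the orientation
    cf[c("a", "d")] <- cf[c("d", "a")]
    cf["b"] <- -cf["b"]
  }
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]), d = unname(cf["d"]),
                 residual_sd = sqrt(best$rss / max(length(y) - 4, 1)),
                 converged = TRUE),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: a=%.4g b=%.4g c=%.4g d=%.4g (residual sd %.3g)\n",
              x$a, x$b, x$c, x$d, x$residual_sd))
  invisible(x)
}

#' Invert a 4PL curve
#'
#' \eqn{x = c\,((a-d)/(y-d) - 1)^{1/b}}. ODs outside a guard band of
#' the asymptote range are not back-calculated: above the band the
#' sample must be re-assayed at higher dilution, below it the result
#' is below the limit of quantification.
#'
#' @param fit a `fourpl_fit` (or list with a, b, c, d).
#' @param od observed OD values.
#' @param guard guard band as a fraction of the asymptote range
#'   (default 0.05).
#' @return data.frame with `od`, `concentration` (NA outside range),
#'   and `flag` in `ok` / `above_range` / `below_lloq`.
#' @export
invert_4pl <- function(fit, od, guard = 0.05) {
  rng <- fit$d - fit$a
  lo <- fit$a + guard * rng
  hi <- fit$d - guard * rng
  conc <- rep(NA_real_, length(od))
  flag <- rep("ok", length(od))
  flag[od >= hi] <- "above_range"
  flag[od <= lo] <- "below_lloq"
  in_range <- flag == "ok"
  conc[in_range] <- fit$c *
    ((fit$a - fit$d) / (od[in_range] - fit$d) - 1)^(1 / fit$b)
  data.frame(od = od, concentration = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' Quantify an ELISA plate
#'
#' Fits the 4PL to the standard series (mean OD of duplicates at each
#' ladder concentration), back-calculates each sample well, multiplies
#' by the total dilution of its stage (1:100 stage = x1000 including
#' the 1:10 assay-buffer dilution; 1:2000 stage = x20000), and reports
#' the mean of duplicate concentrations. Samples whose 1:100 wells
#' read above the standard curve are taken from their 1:2000 wells
#' when present and otherwise flagged `reassay`.
#'
#' @param plate data.frame with columns `type` (`standard` /
#'   `sample`), `sample_id`, `dilution_stage` (`1:100` / `1:2000`),
#'   `concentration` (standards only), `od450`.
#' @param cv_threshold duplicate coefficient-of-variation above which
#'   a `high_cv` flag is raised.
#' @param guard guard band passed to [invert_4pl()].
#' @return data.frame `sample_id`, `units_per_ml`, `dilution_stage`,
#'   `flag`; the 4PL fit is attached as attribute `fit`.
#' @export
quantify_elisa <- function(plate, cv_threshold = 0.25, guard = 0.05) {
  need <- c("type", "sample_id", "dilution_stage", "od450")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stopf("plate missing columns: %s", paste(miss, collapse = ", "))
  std <- plate[plate$type == "standard", ]
  if (!nrow(std)) stopf("plate has no standard wells")
  agg <- aggregate(od450 ~ concentration, std, mean)
  fit <- fit_4pl(agg$concentration, agg$od450)

  dil_mult <- c("1:100" = 1000, "1:2000" = 20000)
  smp <- plate[plate$type == "sample", ]
  out <- lapply(split(smp, smp$sample_id), function(sw) {
    res <- list(sample_id = sw$sample_id[1], units_per_ml = NA_real_,
                dilution_stage = NA_character_, flag = "")
    for (stage in c("1:100", "1:2000")) {
      wells <- sw[sw$dilution_stage == stage, ]
      if (!nrow(wells)) next
      inv <- invert_4pl(fit, wells$od450, guard = guard)
      if (any(inv$flag == "above_range")) {
        if (stage == "1:100") next       # fall through to 1:2000 wells
        res$flag <- "above_range"
        break
      }
      if (all(inv$flag == "below_lloq")) {
        res$units_per_ml <- NA_real_
        res$dilution_stage <- stage
        res$flag <- "below_lloq"
        break
      }
      conc <- inv$concentration * dil_mult[[stage]]
      conc <- conc[is.finite(conc)]
      res$units_per_ml <- mean(conc)
      res$dilution_stage <- stage
      if (length(conc) > 1 && sd(conc) / mean(conc) > cv_threshold)
        res$flag <- "high_cv"
      break
    }
    if (is.na(res$units_per_ml) && res$flag == "") res$flag <- "reassay"
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
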