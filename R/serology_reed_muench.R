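#' Reed-Muench TCID50 from an endpoint titration
#'
#' Wells are scored infected/uninfected at each dilution of a serial
#' ladder. Infected counts are accumulated toward higher virus
#' concentration (a well infected at a weak dose would also be
#' infected at a stronger one) and uninfected counts toward lower
#' concentration; the cumulative percent infected at each dilution is
#' A/(A+B). The 50% endpoint lies between the bracketing dilutions:
#' with proportionate distance
#' \deqn{PD = \frac{\%above - 50}{\%above - \%below},}
#' \eqn{\log_{10}(endpoint\ dilution) = \log_{10}(dilution\ above) -
#' PD \cdot \log_{10}(step)}. The titer per mL scales the reciprocal
#' endpoint dilution by the inoculum volume.
#'
#' @param plate data.frame with columns `dilution` (dilution factor as
#'   a fraction, e.g. 1e-3, or reciprocal > 1 — detected
#'   automatically), `infected`, `total`; rows ordered from most to
#'   least concentrated.
#' @param inoculum_volume_ml volume plated per well (mL).
#' @return list with `log10_endpoint_dilution`, `tcid50_per_ml`,
#'   `bound` (`"exact"`, `"greater_than"`, `"less_than"`), and the
#'   cumulative table.
#' @export
reed_muench_tcid50 <- function(plate, inoculum_volume_ml = 0.1) {
  need <- c("dilution", "infected", "total")
  if (!all(need %in% names(plate)))
    stopf("plate needs columns: %s", paste(need, collapse = ", "))
  if (any(plate$infected > plate$total) || any(plate$infected < 0))
    stopf("infected counts must lie in [0, total]")
  dil <- plate$dilution
  ## normalise to dilution fractions < 1 (10^-k); accept reciprocals
  if (all(dil > 1)) dil <- 1 / dil
  ord <- order(dil, decreasing = TRUE)       # most concentrated first
  dil <- dil[ord]
  inf <- plate$infected[ord]
  uninf <- plate$total[ord] - inf
  cum_inf <- rev(cumsum(rev(inf)))           # toward higher concentration
  cum_uninf <- cumsum(uninf)                 # toward lower concentration
  pct <- 100 * cum_inf / (cum_inf + cum_uninf)
  tab <- data.frame(dilution = dil, infected = inf, uninfected = uninf,
                    cum_infected = cum_inf, cum_uninfected = cum_uninf,
                    percent_infected = pct)

  above <- which(pct >= 50)
  below <- which(pct < 50)
  if (!length(above)) {
    return(list(log10_endpoint_dilution = log10(dil[1]),
                tcid50_per_ml = (1 / dil[1]) / inoculum_volume_ml,
                bound = "less_than", table = tab))
  }
  if (!length(below)) {
    return(list(log10_endpoint_dilution = log10(dil[length(dil)]),
                tcid50_per_ml = (1 / dil[length(dil)]) / inoculum_volume_ml,
                bound = "greater_than", table = tab))
  }
  i <- max(above)                            # last >=50 in the ladder
  if (pct[i] == 50) {
    lg <- log10(dil[i])
  } else {
    j <- i + 1
    pd <- (pct[i] - 50) / (pct[i] - pct[j])
    step <- dil[i] / dil[j]                  # > 1 (e.g. 10 for ten-fold)
    lg <- log10(dil[i]) - pd * log10(step)
  }
  list(log10_endpoint_dilution = lg,
       tcid50_per_ml = (1 / 10^lg) / inoculum_volume_ml,
       bound = "exact", table = tab)
}
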