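#' Simulate an ELISA plate
#'
#' Generates a standard series as a two-fold dilution ladder of the
#' 150,000 units/mL standard in duplicate, plus duplicate sample wells
#' for each true concentration at the requested dilution stage(s). The
#' OD of a well at effective concentration x is `4PL(x)` plus Gaussian
#' noise, clipped to the instrument range. A sample's effective
#' concentration at the 1:100 stage is `true / 1000` (the 1:100
#' pre-dilution times the 1:10 on-plate assay-buffer dilution) and
#' `true / 20000` at the 1:2000 stage.
#'
#' @param true_concentrations named vector of true sample
#'   concentrations (units/mL), names used as sample ids.
#' @param fourpl_params list/vector with `a`, `b`, `c`, `d`.
#' @param dilution_scheme character subset of `c("1:100", "1:2000")`;
#'   wells are laid down for every listed stage.
#' @param noise_sd Gaussian OD noise sd (0 allowed for exact
#'   round-trip checks; negative rejected).
#' @param seed integer seed.
#' @param standard_top top standard concentration (units/mL).
#' @param n_standards ladder length.
#' @param od_range instrument clipping range.
#' @return data.frame: `well`, `row`, `col`, `type`, `sample_id`,
#'   `dilution_stage`, `concentration` (standards), `od450`. The
#'   generating parameters are attached as attribute `params`.
#' @export
simulate_elisa_plate <- function(true_concentrations,
                                 fourpl_params = list(a = 0.05, b = 1.2,
                                                      c = 13000, d = 3.8),
                                 dilution_scheme = c("1:100", "1:2000"),
                                 noise_sd = 0.02, seed = 1L,
                                 standard_top = 150000, n_standards = 8,
                                 od_range = c(0, 4)) {
  if (any(true_concentrations <= 0)) stopf("concentrations must be positive")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  dilution_scheme <- match.arg(dilution_scheme, c("1:100", "1:2000"),
                               several.ok = TRUE)
  if (is.null(names(true_concentrations)))
    names(true_concentrations) <- sprintf("S%02d", seq_along(true_concentrations))
  set.seed(seed)
  p <- fourpl_params
  std_conc <- standard_top / 2^(seq_len(n_standards) - 1)
  dil_mult <- c("1:100" = 1000, "1:2000" = 20000)

  rows <- list()
  for (k in seq_along(std_conc)) {
    for (rep_i in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        type = "standard", sample_id = sprintf("STD%02d", k),
        dilution_stage = NA_character_, concentration = std_conc[k],
        true_od = fourpl(std_conc[k], p$a, p$b, p$c, p$d))
    }
  }
  for (id in names(true_concentrations)) {
    for (stage in dilution_scheme) {
      eff <- true_concentrations[[id]] / dil_mult[[stage]]
      for (rep_i in 1:2) {
        rows[[length(rows) + 1]] <- data.frame(
          type = "sample", sample_id = id, dilution_stage = stage,
          concentration = NA_real_,
          true_od = fourpl(eff, p$a, p$b, p$c, p$d))
      }
    }
  }
  plate <- do.call(rbind, rows)
  n <- nrow(plate)
  od <- plate$true_od + rnorm(n, 0, noise_sd)
  plate$od450 <- pmin(pmax(od, od_range[1]), od_range[2])
  plate$true_od <- NULL
  plate$well <- seq_len(n)
  plate$row <- LETTERS[((plate$well - 1) %/% 12) %% 8 + 1]
  plate$col <- (plate$well - 1) %% 12 + 1
  plate <- plate[, c("well", "row", "col", "type", "sample_id",
                     "dilution_stage", "concentration", "od450")]
  attr(plate, "params") <- list(fourpl = p, noise_sd = noise_sd,
                                true_concentrations = true_concentrations)
  plate
}

#' Simulate a pseudovirus neutralization plate
#'
#' Expected percent neutralization at reciprocal dilution d follows a
#' logistic in log-dilution, `100 / (1 + (d / id50)^h)`, reaching 50%
#' at the true ID50. Serum wells are laid down in quadruplicate with
#' multiplicative noise of coefficient of variation `noise_cv`;
#' virus-only and cell-only control wells are included.
#'
#' @param true_id50 named vector of true ID50s (reciprocal dilution).
#' @param hill_slope logistic slope h (> 0).
#' @param dilution_series reciprocal dilutions, starting at 20.
#' @param virus_only_rlu expected virus-only signal.
#' @param cell_only_rlu expected cell-only background.
#' @param noise_cv multiplicative noise CV (>= 0).
#' @param seed integer seed.
#' @param n_replicates wells per serum dilution.
#' @return data.frame: `well`, `type` (`serum` / `virus_only` /
#'   `cell_only`), `sample_id`, `reciprocal_dilution`, `rlu`.
#' @export
simulate_neutralization_plate <- function(true_id50, hill_slope = 1.5,
                                          dilution_series = 20 * 3^(0:7),
                                          virus_only_rlu = 30000,
                                          cell_only_rlu = 300,
                                          noise_cv = 0.05, seed = 1L,
                                          n_replicates = 4) {
  if (!length(dilution_series)) stopf("empty dilution series")
  if (dilution_series[1] != 20)
    stopf("dilution series must start at the 1:20 input dilution")
  if (any(true_id50 <= 0)) stopf("true_id50 must be positive")
  if (noise_cv < 0) stopf("noise_cv must be non-negative")
  if (is.null(names(true_id50)))
    names(true_id50) <- sprintf("S%02d", seq_along(true_id50))
  set.seed(seed)
  noisy <- function(mu, n) mu * (1 + rnorm(n, 0, noise_cv))
  rows <- list(
    data.frame(type = "virus_only", sample_id = NA_character_,
               reciprocal_dilution = NA_real_,
               rlu = noisy(virus_only_rlu, n_replicates)),
    data.frame(type = "cell_only", sample_id = NA_character_,
               reciprocal_dilution = NA_real_,
               rlu = noisy(cell_only_rlu, n_replicates)))
  for (id in names(true_id50)) {
    for (d in dilution_series) {
      pn <- 100 / (1 + (d / true_id50[[id]])^hill_slope)
      mu <- virus_only_rlu * (1 - pn / 100)
      rows[[length(rows) + 1]] <- data.frame(
        type = "serum", sample_id = id, reciprocal_dilution = d,
        rlu = noisy(mu, n_replicates))
    }
  }
  plate <- do.call(rbind, rows)
  plate$rlu <- pmax(plate$rlu, 0)
  plate <- cbind(well = seq_len(nrow(plate)), plate)
  attr(plate, "params") <- list(true_id50 = true_id50,
                                hill_slope = hill_slope,
                                noise_cv = noise_cv)
  plate
}

#' Build neutralization curves from a plate
#'
#' @param plate a plate data.frame as produced by
#'   [simulate_neutralization_plate()] or read from CSV.
#' @return named list of [neut_curve()] objects, one per serum sample.
#' @export
neut_curves_from_plate <- function(plate) {
  v0 <- plate$rlu[plate$type == "virus_only"]
  c0 <- plate$rlu[plate$type == "cell_only"]
  if (!length(c0)) c0 <- 0
  serum <- plate[plate$type == "serum", ]
  lapply(split(serum, serum$sample_id), function(sw) {
    dils <- sort(unique(sw$reciprocal_dilution))
    rlu <- t(vapply(dils, function(d) sw$rlu[sw$reciprocal_dilution == d],
                    numeric(sum(sw$reciprocal_dilution == dils[1]))))
    neut_curve(sw$sample_id[1], dils, rlu, v0, c0)
  })
}

#' Simulate an endpoint titration plate
#'
#' Virus diluted 1:10 then five-fold for nine dilutions, six wells
#' each. The probability a well is infected at dose D TCID50-units is
#' `1 - exp(-log(2) * D)` (so one TCID50 infects half the wells).
#'
#' @param tcid50_per_ml true titer.
#' @param inoculum_volume_ml volume per well.
#' @param n_dilutions,n_wells ladder length and replicates.
#' @param seed integer seed.
#' @return data.frame `dilution_exponent` (log10 of the dilution
#'   fraction), `dilution`, `infected`, `total`.
#' @export
simulate_titration_plate <- function(tcid50_per_ml, inoculum_volume_ml = 0.1,
                                     n_dilutions = 9, n_wells = 6, seed = 1L) {
  set.seed(seed)
  dil <- (1 / 10) * (1 / 5)^(seq_len(n_dilutions) - 1)
  dose <- tcid50_per_ml * inoculum_volume_ml * dil
  p_inf <- 1 - exp(-log(2) * dose)
  inf <- rbinom(n_dilutions, n_wells, p_inf)
  data.frame(dilution_exponent = log10(dil), dilution = dil,
             infected = inf, total = n_wells)
}
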