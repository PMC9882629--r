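#' Default clinical-lab distributions
#'
#' Monthly pre-vaccination laboratory values for the dialysis cohort
#' are drawn from normal distributions with the cohort means and
#' standard deviations below (ferritin ng/mL, transferrin saturation
#' %, albumin g/dL, WBC and differential k/uL, hemoglobin g/dL, URR as
#' a fraction), truncated at physiologic zero.
#'
#' @return data.frame with `analyte`, `mean`, `sd`.
#' @export
default_lab_params <- function() {
  data.frame(
    analyte = c("urr", "ferritin", "transferrin_sat", "albumin",
                "wbc", "hgb", "lymphocytes", "neutrophils",
                "monocytes", "eosinophils"),
    mean = c(0.74, 838, 38, 4.1, 6.0, 10.5, 1.5, 3.7, 0.5, 0.2),
    sd   = c(0.052, 550, 13, 0.40, 2.1, 1.5, 0.7, 1.5, 0.2, 0.2),
    stringsAsFactors = FALSE)
}

#' Declare a planted module effect
#'
#' @param module_id module identifier (e.g. `"M03"`).
#' @param group `"HC"`, `"HD"` or `"both"`.
#' @param timepoint post-dose timepoint label the effect acts at.
#' @param log2_fold_change planted effect size (log2).
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(module_id, group, timepoint, log2_fold_change) {
  if (!group %in% c("HC", "HD", "both")) stopf("group must be HC, HD or both")
  if (grepl("D0$", timepoint))
    stopf("planted effects must act at a post-dose timepoint, not %s", timepoint)
  structure(list(module_id = module_id, group = group,
                 timepoint = timepoint,
                 log2_fold_change = log2_fold_change),
            class = "planted_effect")
}

default_planted_effects <- function() {
  list(planted_effect("M01", "both", "V1D7", 1.5),
       planted_effect("M02", "both", "V2D7", 1.5),
       planted_effect("M03", "both", "V2D7", -1.2))
}

#' Simulation configuration for the synthetic vaccination cohort
#'
#' Defines the study conditions the generator emulates: two cohorts
#' (controls HC sampled at V1D0/V1D1/V1D7/V2D0/V2D1/V2D7, dialysis HD
#' at V1D0/V1D2/V1D7/V2D0/V2D2/V2D7), ~20 subjects per group,
#' gene-level negative-binomial counts with log-normal subject
#' baselines, a mean-dispersion trend \eqn{\alpha(\mu) = a_0 +
#' a_1/\mu}, planted module effects at chosen group/timepoint
#' combinations, antibody titers generated from a linear model on the
#' per-subject realised module changes plus a SARS-CoV-2-history
#' offset, monthly clinical labs from the cohort's published
#' distributions, and ELISA / neutralization plates from known
#' forward models.
#'
#' @param n_subjects_per_group subjects per cohort.
#' @param n_genes genes in the count matrix.
#' @param n_modules number of (default disjoint) modules.
#' @param module_size_range integer pair within `[5, n_genes]`.
#' @param timepoints named list of per-group ordered timepoint labels.
#' @param baseline_log_mean mean/sd of per-gene baseline on the
#'   natural-log scale.
#' @param dispersion_trend `c(a0, a1)` of the simulated trend.
#' @param subject_sd sd of log-scale subject random intercepts.
#' @param effect_subject_sd sd of the per-subject multiplier on
#'   planted effects (links transcriptome to titers).
#' @param planted_effects list of [planted_effect()] objects.
#' @param titer_model list: `intercept` (log units/mL at V2D7),
#'   `slopes` (named per-module, on the subject's realised log2
#'   module change), `covid_history_offset` (log scale), `noise_sd`,
#'   `baseline_intercept` (log V1D0 titer), `m6_decay` (log drop from
#'   V2D7 to M6), `m6_missing_prob`.
#' @param covid_history_prob named per-group probability of prior
#'   infection.
#' @param lab_params data.frame as [default_lab_params()].
#' @param max_module_overlap maximum tolerated fraction of shared
#'   genes between modules (user-supplied memberships only; default
#'   sampling is disjoint).
#' @param seed integer root seed; every draw derives from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_subjects_per_group = 20,
                       n_genes = 2000,
                       n_modules = 8,
                       module_size_range = c(20, 40),
                       timepoints = list(
                         HC = c("V1D0", "V1D1", "V1D7", "V2D0", "V2D1", "V2D7"),
                         HD = c("V1D0", "V1D2", "V1D7", "V2D0", "V2D2", "V2D7")),
                       baseline_log_mean = c(mean = 4, sd = 1.5),
                       dispersion_trend = c(a0 = 0.05, a1 = 2),
                       subject_sd = 0.3,
                       effect_subject_sd = 0.3,
                       planted_effects = default_planted_effects(),
                       titer_model = list(intercept = log(15000),
                                          slopes = c(M02 = 1.0),
                                          covid_history_offset = 1.5,
                                          noise_sd = 0.6,
                                          baseline_intercept = log(60),
                                          m6_decay = log(3),
                                          m6_missing_prob = 0.1),
                       covid_history_prob = c(HC = 0.25, HD = 0.4),
                       lab_params = default_lab_params(),
                       max_module_overlap = 0.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$module_size_range[1] < 5 || cfg$module_size_range[2] > cfg$n_genes ||
      cfg$module_size_range[1] > cfg$module_size_range[2])
    stopf("module_size_range must lie within [5, n_genes]")
  if (cfg$n_modules * cfg$module_size_range[2] > cfg$n_genes)
    stopf("modules cannot be disjoint: n_modules x max size exceeds n_genes")
  sds <- c(cfg$baseline_log_mean["sd"], cfg$subject_sd,
           cfg$titer_model$noise_sd, cfg$lab_params$sd)
  if (any(sds <= 0)) stopf("all standard deviations must be positive")
  for (g in names(cfg$timepoints))
    if (anyDuplicated(cfg$timepoints[[g]]))
      stopf("timepoint labels must be unique within group %s", g)
  for (pe in cfg$planted_effects) {
    if (!inherits(pe, "planted_effect")) stopf("planted_effects must be planted_effect objects")
    tps <- unique(unlist(cfg$timepoints))
    if (!pe$timepoint %in% tps)
      stopf("planted effect timepoint %s not in design", pe$timepoint)
  }
  mod_ids <- sprintf("M%02d", seq_len(cfg$n_modules))
  for (pe in cfg$planted_effects)
    if (!pe$module_id %in% mod_ids)
      stopf("planted effect refers to unknown module %s", pe$module_id)
  structure(cfg, class = "sim_config")
}
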