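#' Simulate a complete two-cohort vaccination study
#'
#' Generates every pipeline input with the statistical structure the
#' downstream analysis assumes: a gene x sample NB count matrix with
#' log-normal subject baselines and per-sample size factors drawn
#' log-uniform in [0.5, 2]; disjoint gene modules with planted
#' per-group / per-timepoint log2 fold changes (modulated per subject
#' so that transcriptomic change genuinely drives the simulated
#' titers); antibody titers from a linear model on the realised module
#' changes plus a SARS-CoV-2-history offset; monthly clinical labs;
#' and ELISA / neutralization / titration plates from known forward
#' models. The full ground truth is returned (and serialised
#' alongside the outputs by [write_cohort()]). Identical configs give
#' bit-identical bundles.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_cohort`: `counts`, `sample_info`,
#'   `gene_sets`, `titers`, `labs`, `elisa_plates` (per timepoint),
#'   `neut_plates` (per timepoint), `titration_plate`, and
#'   `ground_truth`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  set.seed(config$seed)
  G <- config$n_genes
  npg <- config$n_subjects_per_group
  genes <- sprintf("G%05d", seq_len(G))
  groups <- names(config$timepoints)

  ## --- modules: disjoint membership by default -----------------------
  mod_ids <- sprintf("M%02d", seq_len(config$n_modules))
  size_choices <- config$module_size_range[1]:config$module_size_range[2]
  sizes <- size_choices[sample.int(length(size_choices),
                                   config$n_modules, replace = TRUE)]
  pool <- sample(genes)
  membership <- list()
  off <- 0
  for (k in seq_len(config$n_modules)) {
    membership[[mod_ids[k]]] <- sort(pool[(off + 1):(off + sizes[k])])
    off <- off + sizes[k]
  }
  check_module_overlap(membership, config$max_module_overlap)
  fam_pool <- c("B cells", "cell cycle", "DC/antigen presentation",
                "IFN type I", "myeloid/inflammation", "T/NK cells", "others")
  families <- setNames(rep_len(fam_pool, config$n_modules), mod_ids)
  gene_sets <- gene_set_collection(membership, families)

  ## --- subjects, samples ---------------------------------------------
  subjects <- data.frame(
    group = rep(groups, each = npg),
    stringsAsFactors = FALSE)
  subjects$subject_id <- paste0(subjects$group,
                                sprintf("%02d", rep(seq_len(npg), length(groups))))
  subjects <- subjects[, c("subject_id", "group")]
  subjects$covid_history <-
    runif(nrow(subjects)) < config$covid_history_prob[subjects$group]
  subjects$age <- round(rnorm(nrow(subjects), 54, 12))
  subjects$gender <- sample(c("male", "female"), nrow(subjects), TRUE)
  race_p <- list(HC = c(0.15, 0.10, 0.40, 0.30, 0.05),
                 HD = c(0.50, 0.05, 0.10, 0.35, 0.00))
  races <- c("Black/African American", "Asian/Pacific Islander",
             "White/Caucasian", "Hispanic/Latinx", "Other")
  subjects$race <- vapply(subjects$group, function(g)
    sample(races, 1, prob = race_p[[g]]), "")
  subjects$ethnicity <- ifelse(subjects$race == "Hispanic/Latinx",
                               "Hispanic", "Non-Hispanic")

  sample_info <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    tps <- config$timepoints[[subjects$group[i]]]
    data.frame(sample_id = paste0(subjects$subject_id[i], "_", tps),
               subject_id = subjects$subject_id[i],
               group = subjects$group[i],
               timepoint = tps,
               covid_history = subjects$covid_history[i],
               stringsAsFactors = FALSE)
  }))
  rownames(sample_info) <- NULL
  J <- nrow(sample_info)

  ## --- count model ----------------------------------------------------
  baseline <- rnorm(G, config$baseline_log_mean["mean"],
                    config$baseline_log_mean["sd"])
  subj_int <- setNames(rnorm(nrow(subjects), 0, config$subject_sd),
                       subjects$subject_id)
  size_factors <- setNames(exp(runif(J, log(0.5), log(2))),
                           sample_info$sample_id)
  ## per-subject modulation of planted effects (ties counts to titers)
  r_mult <- matrix(rnorm(nrow(subjects) * config$n_modules, 1,
                         config$effect_subject_sd),
                   nrow(subjects), config$n_modules,
                   dimnames = list(subjects$subject_id, mod_ids))

  log_mu <- matrix(baseline, G, J) +
    matrix(subj_int[sample_info$subject_id], G, J, byrow = TRUE)
  module_change <- matrix(0, nrow(subjects), config$n_modules,
                          dimnames = dimnames(r_mult))
  for (pe in config$planted_effects) {
    g_rows <- match(membership[[pe$module_id]], genes)
    in_grp <- if (pe$group == "both") rep(TRUE, J)
              else sample_info$group == pe$group
    cols <- which(in_grp & sample_info$timepoint == pe$timepoint)
    if (!length(cols)) next
    eff <- pe$log2_fold_change *
      r_mult[sample_info$subject_id[cols], pe$module_id]
    log_mu[g_rows, cols] <- log_mu[g_rows, cols] +
      matrix(log(2) * eff, length(g_rows), length(cols), byrow = TRUE)
    subj_rows <- if (pe$group == "both") seq_len(nrow(subjects))
                 else which(subjects$group == pe$group)
    module_change[subj_rows, pe$module_id] <-
      module_change[subj_rows, pe$module_id] +
      pe$log2_fold_change * r_mult[subj_rows, pe$module_id]
  }
  mu <- sweep(exp(log_mu), 2, size_factors, "*")
  a0 <- config$dispersion_trend["a0"]; a1 <- config$dispersion_trend["a1"]
  alpha <- a0 + a1 / mu
  counts <- matrix(rnbinom(G * J, mu = mu, size = 1 / alpha), G, J,
                   dimnames = list(genes, sample_info$sample_id))
  storage.mode(counts) <- "integer"

  ## --- titers ---------------------------------------------------------
  tm <- config$titer_model
  slopes <- setNames(rep(0, config$n_modules), mod_ids)
  if (length(tm$slopes)) slopes[names(tm$slopes)] <- tm$slopes
  hist_off <- tm$covid_history_offset * subjects$covid_history
  log_v2d7 <- tm$intercept + drop(module_change %*% slopes) + hist_off +
    rnorm(nrow(subjects), 0, tm$noise_sd)
  log_v1d0 <- (tm$baseline_intercept %||% log(60)) + hist_off +
    rnorm(nrow(subjects), 0, tm$noise_sd)
  log_m6 <- log_v2d7 - (tm$m6_decay %||% log(3)) +
    rnorm(nrow(subjects), 0, tm$noise_sd / 2)
  m6_missing <- runif(nrow(subjects)) < (tm$m6_missing_prob %||% 0.1)
  log_m6[m6_missing] <- NA_real_
  ## neutralization linked to binding titer
  log_id50_v1d0 <- log_v1d0 - 12.3 + rnorm(nrow(subjects), 0, 0.3)
  log_id50_v2d7 <- log_v2d7 - 12.3 + rnorm(nrow(subjects), 0, 0.3)

  titers <- data.frame(subjects,
                       igg_v1d0 = exp(log_v1d0),
                       igg_v2d7 = exp(log_v2d7),
                       igg_m6 = exp(log_m6),
                       id50_v1d0 = pmax(exp(log_id50_v1d0), 20),
                       id50_v1d0_censored = exp(log_id50_v1d0) < 20,
                       id50_v2d7 = pmax(exp(log_id50_v2d7), 20),
                       id50_v2d7_censored = exp(log_id50_v2d7) < 20,
                       stringsAsFactors = FALSE)

  ## --- monthly clinical labs (HD subjects) ----------------------------
  hd <- subjects[subjects$group == "HD", ]
  labs <- NULL
  if (nrow(hd)) {
    lp <- config$lab_params
    rows <- list()
    for (i in seq_len(nrow(hd))) {
      days_after <- sample(7:21, 1)
      for (k in seq_len(nrow(lp))) {
        pre <- pmax(rnorm(3, lp$mean[k], lp$sd[k]), 0.01)
        post <- median(pre) * exp(rnorm(1, 0, 0.15))
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = hd$subject_id[i], analyte = lp$analyte[k],
          month = c(-3L, -2L, -1L, NA_integer_),
          phase = c("pre", "pre", "pre", "post_v1"),
          days_after_vaccination = c(NA_integer_, NA_integer_,
                                     NA_integer_, days_after),
          value = c(pre, post), stringsAsFactors = FALSE)
      }
    }
    labs <- do.call(rbind, rows)
  }

  ## --- serology plates -------------------------------------------------
  elisa_true <- list(
    V1D0 = setNames(titers$igg_v1d0, subjects$subject_id),
    V2D7 = setNames(titers$igg_v2d7, subjects$subject_id),
    M6 = setNames(titers$igg_m6, subjects$subject_id))
  elisa_plates <- lapply(names(elisa_true), function(tp) {
    conc <- elisa_true[[tp]]
    conc <- conc[is.finite(conc)]
    simulate_elisa_plate(conc, noise_sd = 0.02,
                         seed = derive_seed(config$seed, paste0("elisa", tp)))
  })
  names(elisa_plates) <- names(elisa_true)
  neut_true <- list(V1D0 = setNames(exp(log_id50_v1d0), subjects$subject_id),
                    V2D7 = setNames(exp(log_id50_v2d7), subjects$subject_id))
  neut_plates <- lapply(names(neut_true), function(tp)
    simulate_neutralization_plate(
      neut_true[[tp]], noise_cv = 0.05,
      seed = derive_seed(config$seed, paste0("neut", tp))))
  names(neut_plates) <- names(neut_true)
  titration_plate <- simulate_titration_plate(
    10^4.5, seed = derive_seed(config$seed, "titration"))

  ground_truth <- list(
    seed = config$seed,
    module_membership = membership,
    module_families = as.list(families),
    planted_effects = lapply(config$planted_effects, unclass),
    size_factors = as.list(size_factors),
    subject_intercepts = as.list(subj_int),
    module_change = module_change,
    titer_model = tm,
    dispersion_trend = as.list(config$dispersion_trend),
    true_log_titer_v2d7 = setNames(log_v2d7, subjects$subject_id),
    true_id50 = neut_true,
    elisa_fourpl = attr(elisa_plates[[1]], "params")$fourpl,
    titration_tcid50_per_ml = 10^4.5)

  structure(list(counts = counts,
                 sample_info = sample_info,
                 gene_sets = gene_sets,
                 titers = titers,
                 labs = labs,
                 elisa_plates = elisa_plates,
                 neut_plates = neut_plates,
                 titration_plate = titration_plate,
                 ground_truth = ground_truth,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d genes x %d samples, %d subjects, %d modules (seed %d)\n",
              nrow(x$counts), ncol(x$counts), nrow(x$titers),
              length(x$gene_sets$sets), x$config$seed))
  invisible(x)
}

check_module_overlap <- function(membership, max_overlap) {
  ids <- names(membership)
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    a <- membership[[i]]; b <- membership[[j]]
    ov <- length(intersect(a, b)) / min(length(a), length(b))
    if (ov > max_overlap)
      stopf("modules %s and %s overlap by %.0f%% (> %.0f%% allowed)",
            ids[i], ids[j], 100 * ov, 100 * max_overlap)
  }
  invisible(TRUE)
}

#' Write a simulated cohort bundle to disk
#'
#' Counts as TSV (and optionally an MTX triple), metadata / titers /
#' labs / plates as CSV, gene sets as GMT plus a family CSV, and the
#' ground truth as JSON.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory.
#' @param mtx also write the MatrixMarket triple.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir, mtx = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_counts_tsv(sim$counts, file.path(dir, "counts.tsv")),
    { write.csv(sim$sample_info, file.path(dir, "sample_info.csv"),
                row.names = FALSE); file.path(dir, "sample_info.csv") },
    write_gmt(sim$gene_sets, file.path(dir, "modules.gmt")),
    write_family_map(sim$gene_sets, file.path(dir, "module_families.csv")),
    { write.csv(sim$titers, file.path(dir, "titers.csv"),
                row.names = FALSE); file.path(dir, "titers.csv") })
  if (!is.null(sim$labs)) {
    write.csv(sim$labs, file.path(dir, "labs.csv"), row.names = FALSE)
    paths <- c(paths, file.path(dir, "labs.csv"))
  }
  for (tp in names(sim$elisa_plates)) {
    fn <- file.path(dir, sprintf("elisa_%s.csv", tp))
    write.csv(sim$elisa_plates[[tp]], fn, row.names = FALSE)
    paths <- c(paths, fn)
  }
  for (tp in names(sim$neut_plates)) {
    fn <- file.path(dir, sprintf("neutralization_%s.csv", tp))
    write.csv(sim$neut_plates[[tp]], fn, row.names = FALSE)
    paths <- c(paths, fn)
  }
  write.csv(sim$titration_plate, file.path(dir, "titration.csv"),
            row.names = FALSE)
  paths <- c(paths, file.path(dir, "titration.csv"))
  gt <- sim$ground_truth
  gt$module_change <- as.data.frame(gt$module_change)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, file.path(dir, "ground_truth.json"))
  if (mtx) paths <- c(paths, write_counts_mtx(sim$counts, file.path(dir, "mtx")))
  invisible(paths)
}
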