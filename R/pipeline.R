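#' Pipeline configuration
#'
#' A single configuration drives the whole run: either a simulation
#' config (the bundle is generated in memory) or a set of input paths,
#' plus stage toggles and thresholds. All randomness derives from the
#' single root `seed` via per-stage substreams.
#'
#' @param simulate a [sim_config()] (or NULL when `inputs` given).
#' @param inputs named list of paths: `counts`, `metadata`,
#'   `gene_sets`, `family_map`, and optionally `titers`, `labs`.
#' @param stages character subset of
#'   `c("de", "enrich", "predict", "serology", "stats")`.
#' @param alpha FDR threshold.
#' @param min_set_size minimum gene-set size for enrichment.
#' @param lloq neutralization lower limit of quantification.
#' @param min_total_count DE low-count filter.
#' @param predict_group cohort modelled in the predictor stage.
#' @param enrichment_method `"ranktest"` or `"gsea"`.
#' @param seed root seed.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            stages = c("de", "enrich", "predict",
                                       "serology", "stats"),
                            alpha = 0.05, min_set_size = 5, lloq = 20,
                            min_total_count = 10, predict_group = "HD",
                            enrichment_method = "ranktest", seed = 1L) {
  if (is.null(simulate) && is.null(inputs))
    stopf("either simulate or inputs must be given")
  stages <- match.arg(stages, c("de", "enrich", "predict", "serology",
                                "stats"), several.ok = TRUE)
  if (!is.null(inputs)) {
    if ("enrich" %in% stages && is.null(inputs$gene_sets))
      stopf("enrichment enabled but no gene_sets path configured")
    missing_files <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing_files))
      stopf("input files not found: %s", paste(missing_files, collapse = ", "))
  }
  structure(list(simulate = simulate, inputs = inputs, stages = stages,
                 alpha = alpha, min_set_size = min_set_size, lloq = lloq,
                 min_total_count = min_total_count,
                 predict_group = predict_group,
                 enrichment_method = enrichment_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_inputs <- function(paths) {
  counts <- if (dir.exists(paths$counts)) read_counts_mtx(paths$counts)
            else read_counts_tsv(paths$counts)
  sample_info <- read.csv(paths$metadata, stringsAsFactors = FALSE)
  gene_sets <- if (!is.null(paths$gene_sets))
    read_gene_sets(paths$gene_sets, paths$family_map) else NULL
  titers <- if (!is.null(paths$titers))
    read.csv(paths$titers, stringsAsFactors = FALSE) else NULL
  labs <- if (!is.null(paths$labs))
    read.csv(paths$labs, stringsAsFactors = FALSE) else NULL
  list(counts = counts, sample_info = sample_info, gene_sets = gene_sets,
       titers = titers, labs = labs)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or load) the
#' inputs, differential expression on the nested design, module
#' enrichment per within-group contrast, eigengene and clinical
#' predictor models, serology quantification, cohort statistics —
#' writing per-stage CSV outputs into `output_dir` together with a
#' JSON manifest that records thresholds, the seed, per-stage row
#' counts and an MD5 checksum of every file written. Reruns with an
#' identical config reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param output_dir run directory, created if needed.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, output_dir) {
  if (!inherits(config, "pipeline_config")) stopf("config must be a pipeline_config")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  counts_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      rec <- list(stage = stage, error = conditionMessage(e))
      jsonlite::write_json(rec, file.path(output_dir, "error.json"),
                           auto_unbox = TRUE)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  state <- list()
  row_counts <- list()

  if (!is.null(config$simulate)) {
    sim <- counts_stage("simulate", {
      cfg <- config$simulate
      cfg$seed <- derive_seed(config$seed, "simulate")
      sim <- simulate_cohort(cfg)
      write_cohort(sim, file.path(output_dir, "inputs"))
      sim
    })
    state$sim <- sim
    bundle <- list(counts = sim$counts, sample_info = sim$sample_info,
                   gene_sets = sim$gene_sets, titers = sim$titers,
                   labs = sim$labs)
    row_counts$simulate <- ncol(sim$counts)
  } else {
    bundle <- counts_stage("load", load_inputs(config$inputs))
  }

  if ("de" %in% config$stages) {
    de <- counts_stage("de", de_analysis(
      bundle$counts, bundle$sample_info, alpha = config$alpha,
      min_total_count = config$min_total_count))
    write_de_results(de, file.path(output_dir, "de"))
    state$de <- de
    row_counts$de <- length(de$genes_kept)
  }

  if ("enrich" %in% config$stages && !is.null(state$de) &&
      !is.null(bundle$gene_sets)) {
    enr <- counts_stage("enrich", {
      within <- grep(" vs V[12]D0$", names(state$de$results), value = TRUE)
      tables <- list()
      for (nm in within) {
        res <- state$de$results[[nm]]
        w <- setNames(res$wald, res$gene_id)
        tables[[nm]] <- enrich_contrast(
          w, bundle$gene_sets, method = config$enrichment_method,
          min_size = config$min_set_size,
          seed = derive_seed(config$seed, paste0("enrich", nm)))
      }
      fam <- family_summary(tables, bundle$gene_sets, alpha = config$alpha)
      dir.create(file.path(output_dir, "enrichment"), showWarnings = FALSE)
      for (nm in names(tables))
        write.csv(tables[[nm]],
                  file.path(output_dir, "enrichment",
                            paste0(gsub("[^A-Za-z0-9]+", "_", nm), ".csv")),
                  row.names = FALSE)
      write.csv(fam, file.path(output_dir, "enrichment", "family_summary.csv"),
                row.names = FALSE)
      list(tables = tables, family = fam)
    })
    state$enrichment <- enr
    row_counts$enrich <- sum(vapply(enr$tables, nrow, 0L))
  }

  if ("predict" %in% config$stages && !is.null(state$de) &&
      !is.null(bundle$gene_sets) && !is.null(bundle$titers)) {
    pred <- counts_stage("predict", run_predict_stage(
      state$de, bundle, state$enrichment, config))
    dir.create(file.path(output_dir, "predictors"), showWarnings = FALSE)
    if (!is.null(pred$btm_models))
      write.csv(pred$btm_models,
                file.path(output_dir, "predictors", "btm_titer_models.csv"),
                row.names = FALSE)
    if (!is.null(pred$baseline_models))
      write.csv(pred$baseline_models,
                file.path(output_dir, "predictors", "baseline_clinical_models.csv"),
                row.names = FALSE)
    if (!is.null(pred$lfc_models))
      write.csv(pred$lfc_models,
                file.path(output_dir, "predictors", "lfc_clinical_models.csv"),
                row.names = FALSE)
    state$predictors <- pred
    row_counts$predict <- nrow(pred$btm_models %||% data.frame())
  }

  if ("serology" %in% config$stages && !is.null(state$sim)) {
    ser <- counts_stage("serology", {
      quant <- lapply(names(state$sim$elisa_plates), function(tp) {
        q <- quantify_elisa(state$sim$elisa_plates[[tp]])
        q$timepoint <- tp
        q
      })
      quant <- do.call(rbind, quant)
      id50 <- lapply(names(state$sim$neut_plates), function(tp) {
        curves <- neut_curves_from_plate(state$sim$neut_plates[[tp]])
        do.call(rbind, lapply(curves, function(cv) {
          r <- compute_id50(cv, lloq = config$lloq)
          data.frame(sample_id = cv$sample_id, timepoint = tp,
                     id50 = r$id50, censored = r$censored,
                     method = r$method,
                     qc = paste(r$qc_flags, collapse = ";"),
                     stringsAsFactors = FALSE)
        }))
      })
      id50 <- do.call(rbind, id50)
      tcid <- reed_muench_tcid50(state$sim$titration_plate)
      dir.create(file.path(output_dir, "serology"), showWarnings = FALSE)
      write.csv(quant, file.path(output_dir, "serology", "elisa_titers.csv"),
                row.names = FALSE)
      write.csv(id50, file.path(output_dir, "serology", "id50.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(log10_endpoint_dilution = tcid$log10_endpoint_dilution,
             tcid50_per_ml = tcid$tcid50_per_ml, bound = tcid$bound),
        file.path(output_dir, "serology", "tcid50.json"),
        auto_unbox = TRUE, digits = NA)
      list(elisa = quant, id50 = id50, tcid50 = tcid)
    })
    state$serology <- ser
    row_counts$serology <- nrow(ser$elisa)
  }

  if ("stats" %in% config$stages && !is.null(bundle$titers)) {
    st <- counts_stage("stats", run_stats_stage(bundle$titers, config))
    dir.create(file.path(output_dir, "stats"), showWarnings = FALSE)
    write.csv(st$kruskal, file.path(output_dir, "stats", "kruskal.csv"),
              row.names = FALSE)
    write.csv(st$pairwise, file.path(output_dir, "stats", "pairwise_wilcoxon.csv"),
              row.names = FALSE)
    if (!is.null(st$id50))
      write.csv(st$id50, file.path(output_dir, "stats", "id50_wilcoxon.csv"),
                row.names = FALSE)
    write.csv(st$demographics, file.path(output_dir, "stats", "demographics.csv"),
              row.names = FALSE)
    state$stats <- st
    row_counts$stats <- nrow(st$pairwise)
  }

  files <- list.files(output_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(output_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dialvax")),
    seed = config$seed,
    stages = config$stages,
    thresholds = list(alpha = config$alpha,
                      min_set_size = config$min_set_size,
                      lloq = config$lloq,
                      min_total_count = config$min_total_count),
    row_counts = row_counts,
    files = lapply(files, function(f)
      list(path = sub(paste0("^", output_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(state, list(manifest = manifest)))
}

run_predict_stage <- function(de, bundle, enrichment, config) {
  si <- bundle$sample_info
  titers <- bundle$titers
  grp <- config$predict_group
  si_g <- si[si$group == grp, ]
  if (!nrow(si_g)) stopf("predict_group '%s' has no samples", grp)
  log_titer <- setNames(log(titers$igg_v2d7), titers$subject_id)
  covid <- setNames(titers$covid_history, titers$subject_id)

  btm_rows <- list()
  for (dose in c("V1", "V2")) {
    window <- si_g$sample_id[substr(si_g$timepoint, 1, 2) == dose]
    if (length(window) < 3) next
    eig <- compute_eigengenes(de$vst, bundle$gene_sets, window)
    base_tp <- paste0(dose, "D0")
    post_tps <- setdiff(unique(si_g$timepoint[substr(si_g$timepoint, 1, 2) == dose]),
                        base_tp)
    for (tp in post_tps) {
      dl <- delta_eigengene(eig, si_g, base_tp, tp)
      enriched <- rownames(eig$scores)
      if (!is.null(enrichment)) {
        key <- sprintf("%s %s vs %s", grp, tp, base_tp)
        if (key %in% names(enrichment$tables)) {
          et <- enrichment$tables[[key]]
          enriched <- et$set_id[et$fdr < config$alpha]
        }
      }
      enriched <- intersect(enriched, colnames(dl$delta))
      if (!length(enriched)) next
      m <- btm_titer_models(dl$delta, log_titer, covid, enriched)
      if (nrow(m)) {
        m$timepoint <- tp
        btm_rows[[length(btm_rows) + 1]] <- m
      }
    }
  }
  btm_models <- if (length(btm_rows)) do.call(rbind, btm_rows) else NULL

  baseline_models <- lfc_models <- NULL
  if (!is.null(bundle$labs)) {
    baselines <- baseline_clinical(bundle$labs)
    outcomes <- list(v2d7 = log_titer)
    if ("igg_m6" %in% names(titers))
      outcomes$m6 <- setNames(log(titers$igg_m6), titers$subject_id)
    baseline_models <- baseline_clinical_models(baselines, outcomes, covid)
    lfcs <- lab_lfc(bundle$labs)
    covdf <- data.frame(covid_history = titers$covid_history,
                        row.names = titers$subject_id)
    lfc_models <- lfc_clinical_models(lfcs, outcomes, covdf)
  }
  list(btm_models = btm_models, baseline_models = baseline_models,
       lfc_models = lfc_models)
}

run_stats_stage <- function(titers, config) {
  long <- do.call(rbind, lapply(c("igg_v1d0", "igg_v2d7", "igg_m6"),
    function(cl) if (cl %in% names(titers)) data.frame(
      subject_id = titers$subject_id, group = titers$group,
      timepoint = toupper(sub("igg_", "", cl)), value = titers[[cl]],
      stringsAsFactors = FALSE)))
  kw <- do.call(rbind, lapply(unique(long$group), function(g) {
    d <- long[long$group == g & is.finite(long$value), ]
    k <- kruskal_titers(d$value, d$timepoint)
    data.frame(group = g, H = k$H, df = k$df, p = k$p)
  }))
  pw <- do.call(rbind, lapply(unique(long$group), function(g) {
    d <- long[long$group == g & is.finite(long$value), ]
    p <- pairwise_wilcoxon_fdr(d$value, d$timepoint)
    cbind(group = g, p)
  }))
  ## neutralization response: V2D7 vs V1D0 per group, censored ID50s
  ## entering as ties at the LLOQ
  id50 <- NULL
  if (all(c("id50_v1d0", "id50_v2d7") %in% names(titers))) {
    id50_long <- rbind(
      data.frame(group = titers$group, timepoint = "V1D0",
                 value = titers$id50_v1d0),
      data.frame(group = titers$group, timepoint = "V2D7",
                 value = titers$id50_v2d7))
    id50 <- do.call(rbind, lapply(unique(id50_long$group), function(g) {
      d <- id50_long[id50_long$group == g & is.finite(id50_long$value), ]
      p <- pairwise_wilcoxon_fdr(d$value, d$timepoint,
                                 pairs = list(c("V1D0", "V2D7")))
      cbind(group = g, p)
    }))
  }
  demo_cols <- intersect(c("subject_id", "group", "covid_history", "age"),
                         names(titers))
  demo <- demographics_table(titers[, demo_cols])
  list(kruskal = kw, pairwise = pw, id50 = id50, demographics = demo)
}
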