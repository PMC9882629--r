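test_that("identical configs give bit-identical bundles", {
  cfg <- sim_config(n_subjects_per_group = 3, n_genes = 2000, n_modules = 4,
                    module_size_range = c(10, 20),
                    timepoints = list(HC = c("V1D0", "V1D7"),
                                      HD = c("V1D0", "V1D7")),
                    planted_effects = list(planted_effect("M01", "both",
                                                          "V1D7", 1)),
                    seed = 1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$titers, b$titers)
  expect_identical(a$elisa_plates, b$elisa_plates)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("count marginals follow NB(mu, a0 + a1/mu)", {
  ## >= 200 samples, negligible subject variation, no planted effects
  cfg <- sim_config(n_subjects_per_group = 17, n_genes = 200, n_modules = 2,
                    module_size_range = c(5, 8), subject_sd = 1e-6,
                    planted_effects = list(), seed = 21)
  sim <- simulate_cohort(cfg)
  sf <- unlist(sim$ground_truth$size_factors)[colnames(sim$counts)]
  q <- sweep(sim$counts, 2, sf, "/")
  a0 <- 0.05; a1 <- 2
  ratios <- vapply(seq_len(nrow(q)), function(g) {
    mu <- mean(q[g, ])
    ## Var(y_j / s_j) = mu/s_j + alpha(mu) mu^2, averaged over samples
    expected <- mu * mean(1 / sf) + (a0 + a1 / mu) * mu^2
    var(q[g, ]) / expected
  }, 0)
  expect_gt(median(ratios), 0.85)
  expect_lt(median(ratios), 1.15)
})

test_that("covid-history offset propagates to mean log titer", {
  cfg <- sim_config(
    n_subjects_per_group = 100, n_genes = 50, n_modules = 2,
    module_size_range = c(5, 8),
    timepoints = list(HC = c("V1D0", "V1D7"), HD = c("V1D0", "V1D7")),
    planted_effects = list(),
    titer_model = list(intercept = log(3e7), slopes = c(),
                       covid_history_offset = 2.0, noise_sd = 0.6,
                       baseline_intercept = log(3e6), m6_decay = log(3),
                       m6_missing_prob = 0),
    covid_history_prob = c(HC = 0.5, HD = 0.5), seed = 5)
  sim <- simulate_cohort(cfg)
  y <- log(sim$titers$igg_v2d7)
  h <- sim$titers$covid_history
  diff <- mean(y[h]) - mean(y[!h])
  se <- sqrt(var(y[h]) / sum(h) + var(y[!h]) / sum(!h))
  expect_lt(abs(diff - 2.0), 3 * se)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 100, n_modules = 10,
                          module_size_range = c(20, 30)),
               "disjoint")
  expect_error(sim_config(module_size_range = c(2, 10)), "module_size_range")
  expect_error(planted_effect("M01", "both", "V1D0", 1), "post-dose")
  expect_error(sim_config(planted_effects = list(
    planted_effect("M99", "both", "V1D7", 1))), "unknown module")
  expect_error(sim_config(subject_sd = -1), "positive")
})

test_that("simulated ELISA plates honour the 4PL forward model", {
  p <- list(a = 0.05, b = 1.2, c = 13000, d = 3.8)
  ## concentration at curve midpoint: effective well conc = c
  plate <- simulate_elisa_plate(c(S = p$c * 1000), fourpl_params = p,
                                dilution_scheme = "1:100", noise_sd = 0)
  mid <- plate$od450[plate$type == "sample"]
  expect_equal(mid, rep((p$a + p$d) / 2, 2), tolerance = 1e-12)
  ## noiseless round trip through the quantifier
  truth <- c(A = 2e6, B = 5e7)
  pl <- simulate_elisa_plate(truth, fourpl_params = p, noise_sd = 0)
  q <- quantify_elisa(pl)
  expect_equal(q$units_per_ml[match(names(truth), q$sample_id)],
               unname(truth), tolerance = 1e-6)
  expect_error(simulate_elisa_plate(c(A = 100), noise_sd = -0.1),
               "non-negative")
  expect_error(simulate_elisa_plate(c(A = -5)), "must be positive")
})

test_that("simulated neutralization plates invert to their true ID50", {
  pl <- simulate_neutralization_plate(c(S = 160), noise_cv = 0)
  r <- compute_id50(neut_curves_from_plate(pl)[[1]])
  expect_lt(abs(r$id50 / 160 - 1), 0.01)
  expect_false(r$censored)
  ## ID50 below the 1:20 start is censored at the LLOQ
  pl2 <- simulate_neutralization_plate(c(S = 5), noise_cv = 0)
  r2 <- compute_id50(neut_curves_from_plate(pl2)[[1]])
  expect_true(r2$censored)
  expect_equal(r2$id50, 20)
  ## wells at dilution == ID50 sit at 50% neutralization
  pl3 <- simulate_neutralization_plate(c(S = 180), noise_cv = 0)
  serum <- pl3[pl3$type == "serum" & pl3$reciprocal_dilution == 180, ]
  v0 <- mean(pl3$rlu[pl3$type == "virus_only"])
  expect_equal(mean(percent_neutralization(v0, serum$rlu)), 50,
               tolerance = 1e-9)
  expect_error(simulate_neutralization_plate(c(S = 100),
                                             dilution_series = c(40, 120)),
               "1:20")
  expect_error(simulate_neutralization_plate(c(S = 100),
                                             dilution_series = numeric(0)),
               "empty")
})

test_that("written bundles round-trip through the readers", {
  cfg <- small_sim_config(seed = 9, n_subjects = 3, n_genes = 120)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir, mtx = TRUE)
  expect_identical(read_counts_tsv(file.path(dir, "counts.tsv")), sim$counts)
  expect_identical(read_counts_mtx(file.path(dir, "mtx")), sim$counts)
  gs <- read_gene_sets(file.path(dir, "modules.gmt"),
                       file.path(dir, "module_families.csv"))
  expect_identical(gs$sets, sim$gene_sets$sets)
  expect_identical(gs$families, sim$gene_sets$families)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_identical(names(gt$module_membership), names(sim$gene_sets$sets))
})
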