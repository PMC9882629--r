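P4 <- list(a = 0.05, b = 1.2, c = 13000, d = 3.8)

test_that("4PL fits recover noiseless parameters and the midpoint identity", {
  x <- 150000 / 2^(0:7)
  y <- fourpl(x, P4$a, P4$b, P4$c, P4$d)
  f <- fit_4pl(x, y)
  expect_equal(c(f$a, f$b, f$c, f$d), c(P4$a, P4$b, P4$c, P4$d),
               tolerance = 1e-6)
  expect_equal(fourpl(P4$c, P4$a, P4$b, P4$c, P4$d), (P4$a + P4$d) / 2)
  ## ladders sitting on one asymptote are rejected
  flat <- fourpl(1e6 * 2^(0:6), P4$a, P4$b, P4$c, P4$d)
  expect_error(fit_4pl(1e6 * 2^(0:6), flat), "span")
})

test_that("noisy 4PL fits recover the inflection within 5%", {
  x <- rep(150000 / 2^(0:7), each = 2)
  set.seed(12)
  errs <- replicate(100, {
    y <- fourpl(x, P4$a, P4$b, P4$c, P4$d) + rnorm(length(x), 0, 0.02)
    f <- fit_4pl(x, y)
    abs(f$c / P4$c - 1)
  })
  expect_lt(median(errs), 0.05)
})

test_that("4PL inversion round-trips and signals out-of-range ODs", {
  f <- structure(c(P4, list(residual_sd = 0, converged = TRUE)),
                 class = "fourpl_fit")
  expect_equal(invert_4pl(f, (P4$a + P4$d) / 2)$concentration, P4$c)
  x <- c(2000, 5000, 50000)
  inv <- invert_4pl(f, fourpl(x, P4$a, P4$b, P4$c, P4$d))
  expect_equal(inv$concentration, x, tolerance = 1e-9)
  hi <- invert_4pl(f, P4$d - 0.01)
  expect_equal(hi$flag, "above_range")
  expect_true(is.na(hi$concentration))
  lo <- invert_4pl(f, P4$a + 0.01)
  expect_equal(lo$flag, "below_lloq")
})

test_that("plate quantification applies dilution logic and duplicate averaging", {
  truth <- c(lowish = 3e6, strong = 4e8)   # strong saturates at 1:100
  pl <- simulate_elisa_plate(truth, fourpl_params = P4, noise_sd = 0)
  q <- quantify_elisa(pl)
  expect_equal(q$units_per_ml[q$sample_id == "lowish"], 3e6, tolerance = 1e-6)
  expect_equal(q$dilution_stage[q$sample_id == "lowish"], "1:100")
  expect_equal(q$units_per_ml[q$sample_id == "strong"], 4e8, tolerance = 1e-6)
  expect_equal(q$dilution_stage[q$sample_id == "strong"], "1:2000")
  ## reported value is the mean of the duplicate concentrations;
  ## invariant to well order
  f <- attr(q, "fit")
  ods <- fourpl(c(9000, 11000), f$a, f$b, f$c, f$d)
  plate <- rbind(pl[pl$type == "standard", ],
                 data.frame(well = 900:901, row = "H", col = 1:2,
                            type = "sample", sample_id = "dup",
                            dilution_stage = "1:100",
                            concentration = NA, od450 = ods))
  expect_equal(quantify_elisa(plate)$units_per_ml, 10000 * 1000,
               tolerance = 1e-6)
  swapped <- plate[c(nrow(plate):1), ]
  expect_equal(quantify_elisa(swapped)$units_per_ml,
               quantify_elisa(plate)$units_per_ml)
})

test_that("median relative ELISA quantification error stays below 10% with noise", {
  truth <- c(A = 2e6, B = 8e6, C = 3e7)
  errs <- vapply(1:100, function(s) {
    pl <- simulate_elisa_plate(truth, fourpl_params = P4, noise_sd = 0.02,
                               dilution_scheme = "1:100", seed = s)
    q <- quantify_elisa(pl)
    median(abs(q$units_per_ml / truth[q$sample_id] - 1))
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("percent neutralization is the printed formula, unclipped", {
  expect_equal(percent_neutralization(10000, 2500), 75)
  expect_equal(percent_neutralization(8000, 8000), 0)
  expect_equal(percent_neutralization(8000, 0), 100)
  expect_equal(percent_neutralization(8000, 9000), -12.5)
  expect_equal(percent_neutralization(1000, 250),
               percent_neutralization(7000, 1750))
  expect_error(percent_neutralization(0, 100), "positive")
})

test_that("ID50 estimation: exact inverse, interpolation fallback, censoring", {
  pl <- simulate_neutralization_plate(c(S = 320), noise_cv = 0)
  r <- compute_id50(neut_curves_from_plate(pl)[[1]])
  expect_lt(abs(r$id50 / 320 - 1), 0.01)
  ## forced interpolation: 60% at 1:40, 40% at 1:80 -> geometric midpoint
  v0 <- 10000
  pn <- c(80, 60, 40, 20)
  cv <- neut_curve("x", c(20, 40, 80, 160),
                   matrix(rep(v0 * (1 - pn / 100), 2), ncol = 2),
                   virus_only_rlu = rep(v0, 4))
  ri <- compute_id50(cv, estimator = "interpolation")
  expect_equal(ri$id50, 10^((log10(40) + log10(80)) / 2), tolerance = 1e-9)
  expect_equal(ri$method, "interpolation")
  ## a curve peaking at 30% neutralization is censored at the LLOQ
  pn2 <- c(30, 20, 10, 5)
  cv2 <- neut_curve("y", c(20, 40, 80, 160),
                    matrix(rep(v0 * (1 - pn2 / 100), 2), ncol = 2),
                    virus_only_rlu = rep(v0, 4))
  r2 <- compute_id50(cv2)
  expect_true(r2$censored)
  expect_equal(r2$id50, 20)
})

test_that("ID50 is stable under log-dilution reflection of the curve", {
  id50 <- 320; h <- 1.5
  d <- 20 * 3^(0:7)
  pn <- 100 / (1 + (d / id50)^h)
  v0 <- 10000
  mk <- function(dil, pn) neut_curve("s", dil,
                                     matrix(rep(v0 * (1 - pn / 100), 4), ncol = 4),
                                     virus_only_rlu = rep(v0, 4))
  r1 <- compute_id50(mk(d, pn))
  ## reflect dilutions about the ID50 in log space (same logistic curve)
  d2 <- sort(id50^2 / d)
  pn2 <- 100 / (1 + (d2 / id50)^h)
  r2 <- compute_id50(mk(d2, pn2), lloq = min(d2))
  expect_equal(r1$id50, r2$id50, tolerance = 1e-6)
})

test_that("Reed-Muench reproduces the hand-worked endpoint", {
  plate <- data.frame(dilution = 10^-(1:5),
                      infected = c(6, 6, 4, 2, 0), total = 6)
  rm <- reed_muench_tcid50(plate, inoculum_volume_ml = 0.1)
  ## cumulative percentages bracket 50 with 66.7/33.3 at 1e-3/1e-4
  expect_equal(rm$table$percent_infected[3:4], c(75, 25))
  plate2 <- data.frame(dilution = 10^-(1:5),
                       infected = c(6, 6, 3, 1, 0), total = 6)
  rm2 <- reed_muench_tcid50(plate2, inoculum_volume_ml = 0.1)
  pct <- rm2$table$percent_infected
  pd <- (pct[3] - 50) / (pct[3] - pct[4])
  expect_equal(rm2$log10_endpoint_dilution, -3 - pd)
  ## 66.7 / 33.3 bracketing gives PD = 0.5 and endpoint 10^-3.5
  plate3 <- data.frame(dilution = 10^-(2:5),
                       infected = c(4, 2, 2, 0), total = 4)
  rm3 <- reed_muench_tcid50(plate3)
  expect_equal(rm3$table$percent_infected[2:3], c(200 / 3, 100 / 3),
               tolerance = 1e-9)
  expect_equal(rm3$log10_endpoint_dilution, -3.5)
  ## per-mL scaling by the inoculum volume
  expect_equal(reed_muench_tcid50(plate3, 0.1)$tcid50_per_ml,
               10 * reed_muench_tcid50(plate3, 1)$tcid50_per_ml)
})

test_that("Reed-Muench handles exact 50%, bounds, and is monotone", {
  exact <- data.frame(dilution = 10^-(1:3), infected = c(6, 3, 0), total = 6)
  ## cumulative: 9/9, 3/6, 0/6 -> 100, 33.3... crossing above at 1e-1
  r <- reed_muench_tcid50(exact)
  expect_equal(r$bound, "exact")
  all_inf <- data.frame(dilution = 10^-(1:3), infected = 6, total = 6)
  expect_equal(reed_muench_tcid50(all_inf)$bound, "greater_than")
  none <- data.frame(dilution = 10^-(1:3), infected = 0, total = 6)
  expect_equal(reed_muench_tcid50(none)$bound, "less_than")
  expect_error(reed_muench_tcid50(
    data.frame(dilution = 0.1, infected = 7, total = 6)), "lie in")
  ## monotonicity: more infected wells never lowers the titer
  set.seed(13)
  for (i in 1:20) {
    inf <- sort(sample(0:6, 5, TRUE), decreasing = TRUE)
    base <- data.frame(dilution = 10^-(1:5), infected = inf, total = 6)
    bump <- base
    j <- sample(5, 1)
    bump$infected[j] <- min(6, bump$infected[j] + 1)
    expect_gte(reed_muench_tcid50(bump)$tcid50_per_ml,
               reed_muench_tcid50(base)$tcid50_per_ml)
  }
})
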