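test_that("size factors reproduce the median-of-ratios hand oracle", {
  cts <- matrix(c(2L, 8L, 4L, 16L), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ## geometric means 2.828 / 11.314; all per-sample ratios equal
  expect_equal(unname(estimate_size_factors(cts)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)
  ident <- matrix(5L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(unname(estimate_size_factors(ident)), rep(1, 3))
})

test_that("size factors are scale-equivariant up to the free normalisation", {
  ## median-of-ratios factors are defined only up to a common constant:
  ## scaling one column by c rescales its factor by c and the whole
  ## vector by c^(-1/m) through the per-gene geometric means
  si <- paired_layout(3)
  cts <- nb_counts(si, 50, seed = 2)
  m <- ncol(cts)
  sf <- estimate_size_factors(cts)
  cts10 <- cts
  cts10[, 3] <- cts10[, 3] * 10L
  sf10 <- estimate_size_factors(cts10)
  expect_equal(sf10[3], sf[3] * 10 * 10^(-1 / m), tolerance = 1e-12)
  expect_equal(sf10[-3], sf[-3] * 10^(-1 / m), tolerance = 1e-12)
  ## factor ratios are exactly equivariant
  expect_equal(sf10[3] / sf10[1], 10 * sf[3] / sf[1], tolerance = 1e-12)
  zero <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(estimate_size_factors(zero), "pseudo-reference")
})

test_that("nested design is full rank and absorbs subject effects", {
  si <- paired_layout(4)
  des <- nested_design(si)
  expect_equal(qr(des$matrix)$rank, ncol(des$matrix))
  ## scaling one subject's counts (a constant on its log-means) must
  ## leave timepoint contrasts untouched
  ## exact-model counts (zero deviance): a x4 scaling of one subject
  ## lies exactly along its nesting column, so every timepoint
  ## contrast is untouched at the MLE
  mult <- list(HC = 1, HD = 2)
  tmul <- c(V1D0 = 1, V1D7 = 3)
  bases <- c(20L, 30L, 40L, 50L, 60L)
  cts <- t(vapply(seq_len(nrow(si)), function(j) {
    s_i <- as.integer(sub("^\\D+", "", si$subject_id[j]))
    bases * s_i * tmul[[si$timepoint[j]]] * mult[[si$group[j]]]
  }, numeric(5)))
  cts <- t(cts)
  dimnames(cts) <- list(paste0("g", seq_len(5)), si$sample_id)
  storage.mode(cts) <- "integer"
  sf <- setNames(rep(1, nrow(si)), si$sample_id)
  fit1 <- fit_nbglm(cts, sf, des, 0.05, tol = 1e-12)
  shifted <- cts
  cols <- si$sample_id[si$subject_id == "HD02"]
  shifted[, cols] <- shifted[, cols] * 4L
  fit2 <- fit_nbglm(shifted, sf, des, 0.05, tol = 1e-12)
  cvec <- timepoint_contrast(des, "HD", "V1D7", "V1D0")
  expect_lt(max(abs(drop(fit1$beta %*% cvec) - drop(fit2$beta %*% cvec))),
            1e-6)
})

test_that("GLM log2FC matches condition-mean ratios for large counts", {
  ## balanced two-condition design, no nesting, alpha -> 0
  set.seed(4)
  n <- 10
  X <- cbind(intercept = 1, cond = rep(0:1, each = n / 2))
  rownames(X) <- paste0("s", 1:n)
  sf <- setNames(rep(1, n), rownames(X))
  mu <- outer(exp(rnorm(20, 9, 0.3)), sf) *
    matrix(rep(c(1, 2.5), each = n / 2), 20, n, byrow = TRUE)
  cts <- matrix(rnbinom(20 * n, mu = mu, size = 1 / 1e-4), 20, n,
                dimnames = list(paste0("g", 1:20), rownames(X)))
  storage.mode(cts) <- "integer"
  fit <- fit_nbglm(cts, sf, X, 1e-8, tol = 1e-12)
  q <- sweep(cts, 2, sf, "/")
  ratio <- log2(rowMeans(q[, 6:10]) / rowMeans(q[, 1:5]))
  expect_lt(max(abs(fit$beta[, "cond"] / log(2) - ratio)), 1e-3)
})

test_that("all-zero genes are flagged degenerate and excluded from DEGs", {
  si <- paired_layout(3)
  cts <- nb_counts(si, 10, seed = 5)
  cts[1, ] <- 0L
  des <- nested_design(si)
  sf <- setNames(rep(1, nrow(si)), si$sample_id)
  fit <- fit_nbglm(cts, sf, des, 0.1)
  expect_true(fit$degenerate[1])
  res <- wald_contrast(fit, timepoint_contrast(des, "HC", "V1D7", "V1D0"))
  expect_true(is.na(res$p[1]))
  expect_true(all(res$fdr >= res$p, na.rm = TRUE))
})

test_that("contrasts are antisymmetric and zero contrasts give p = 1", {
  si <- paired_layout(4)
  cts <- nb_counts(si, 40, seed = 6)
  des <- nested_design(si)
  sf <- estimate_size_factors(cts)
  fit <- fit_nbglm(cts, sf, des, 0.1)
  cvec <- timepoint_contrast(des, "HD", "V1D7", "V1D0")
  r1 <- wald_contrast(fit, cvec)
  r2 <- wald_contrast(fit, -cvec)
  expect_equal(r2$log2fc, -r1$log2fc)
  expect_equal(r2$wald, -r1$wald)
  expect_equal(r2$p, r1$p)
  expect_equal(r2$fdr, r1$fdr)
  ## a zero contrast is rejected, and all-null p gives zero DEGs
  expect_error(timepoint_contrast(des, "HD", "V1D0", "V1D0"),
               "identically zero")
  expect_equal(count_degs(r1, alpha = 1e-12), 0L)
})

test_that("Wald contrasts agree with an independent NB-GLM implementation", {
  ## same size factors and dispersions handed to both engines
  set.seed(42)
  si <- paired_layout(4)
  des <- nested_design(si)
  X <- des$matrix
  n <- nrow(si)
  sf <- setNames(exp(runif(n, log(0.8), log(1.25))), si$sample_id)
  G <- 30
  alpha <- rep(0.1, G)
  cts <- matrix(0L, G, n, dimnames = list(sprintf("g%02d", 1:G), si$sample_id))
  for (g in 1:G) {
    mu <- sf * exp(drop(X %*% c(5, rnorm(ncol(X) - 1, 0, 0.3))))
    cts[g, ] <- rnbinom(n, mu = mu, size = 1 / alpha[g])
  }
  fit <- fit_nbglm(cts, sf, des, alpha, tol = 1e-12)
  cvec <- timepoint_contrast(des, "HD", "V1D7", "V1D0")
  ours <- wald_contrast(fit, cvec)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(cts, S4Vectors::DataFrame(si),
                                          design = ~1)
    DESeq2::sizeFactors(dds) <- sf
    S4Vectors::mcols(dds)$dispersion <- alpha
    dds <- DESeq2::nbinomWaldTest(dds, modelMatrix = X, betaPrior = FALSE)
    ref <- DESeq2::results(dds, contrast = cvec)
  })
  expect_lt(max(abs(ours$log2fc - ref$log2FoldChange)), 1e-3)
  expect_lt(max(abs(ours$se - ref$lfcSE)), 1e-4)
  expect_gt(cor(ours$wald, ref$stat), 0.99999)
})

test_that("gene-wise dispersion recovery: NB truth within the MAP band", {
  si <- paired_layout(3)
  set.seed(7)
  G <- 2000
  mu <- exp(rnorm(G, 5, 1))
  cts <- matrix(0L, G, nrow(si),
                dimnames = list(sprintf("g%04d", 1:G), si$sample_id))
  for (g in 1:G) cts[g, ] <- rnbinom(nrow(si), mu = mu[g], size = 1 / 0.2)
  sf <- setNames(rep(1, nrow(si)), si$sample_id)
  d <- fit_dispersions(cts, sf, nested_design(si))
  expect_gt(median(d$map_alpha), 0.15)
  expect_lt(median(d$map_alpha), 0.25)
  expect_true(all(d$map_alpha > 0))
})

test_that("Poisson data yields near-zero shrunk dispersions", {
  si <- paired_layout(10)
  set.seed(8)
  G <- 300
  cts <- matrix(rpois(G * nrow(si), 200), G, nrow(si),
                dimnames = list(sprintf("g%03d", 1:G), si$sample_id))
  storage.mode(cts) <- "integer"
  sf <- setNames(rep(1, nrow(si)), si$sample_id)
  d <- suppressWarnings(fit_dispersions(cts, sf, nested_design(si)))
  expect_lt(median(d$map_alpha), 0.01)
})

test_that("single-gene input refuses the trend with a warning", {
  si <- paired_layout(3)
  cts <- nb_counts(si, 1, seed = 9)
  sf <- setNames(rep(1, nrow(si)), si$sample_id)
  expect_warning(d <- fit_dispersions(cts, sf, nested_design(si)),
                 "single-gene")
  expect_true(is.na(d$trend_coeffs[["a0"]]))
  expect_equal(d$map_alpha, d$genewise_alpha)
})

test_that("VST is monotone and reduces to log2 spacing at a1 = 0", {
  x <- matrix(0:500, 1, 501,
              dimnames = list("g", paste0("s", 0:500)))
  storage.mode(x) <- "integer"
  sf <- setNames(rep(1, 501), colnames(x))
  v <- vst_transform(x, sf, c(a0 = 0.1, a1 = 2))
  expect_true(all(diff(drop(v)) > 0))
  big <- matrix(c(100000L, 200000L), 1, 2,
                dimnames = list("g", c("s1", "s2")))
  v2 <- vst_transform(big, setNames(c(1, 1), c("s1", "s2")),
                      c(a0 = 0.05, a1 = 0))
  expect_equal(v2[1, 2] - v2[1, 1], 1, tolerance = 1e-3)
  expect_warning(vst_transform(big, setNames(c(1, 1), c("s1", "s2")),
                               c(a0 = -1, a1 = 0)), "falling back")
})

test_that("VST flattens variance across the mean range", {
  si <- paired_layout(10)
  set.seed(10)
  G <- 1000
  mu <- exp(seq(log(10), log(10000), length.out = G))
  a0 <- 0.05; a1 <- 2
  cts <- matrix(0L, G, nrow(si),
                dimnames = list(sprintf("g%04d", 1:G), si$sample_id))
  for (g in 1:G)
    cts[g, ] <- rnbinom(nrow(si), mu = mu[g], size = 1 / (a0 + a1 / mu[g]))
  sf <- setNames(rep(1, nrow(si)), si$sample_id)
  v <- vst_transform(cts, sf, c(a0 = a0, a1 = a1))
  sds <- apply(v, 1, sd)
  decile_sd <- tapply(sds, cut(seq_len(G), 10), mean)
  expect_lt(max(decile_sd) / min(decile_sd) - 1, 0.25)
})

test_that("planted strong effects are detected with expected power", {
  ## 100 strongly perturbed genes at 20 subjects per group
  cfg <- sim_config(n_subjects_per_group = 20, n_genes = 1000,
                    n_modules = 4, module_size_range = c(25, 25),
                    timepoints = list(HC = c("V1D0", "V1D7"),
                                      HD = c("V1D0", "V1D7")),
                    baseline_log_mean = c(mean = 5, sd = 1),
                    planted_effects = list(
                      planted_effect("M01", "both", "V1D7", 2),
                      planted_effect("M02", "both", "V1D7", 2),
                      planted_effect("M03", "both", "V1D7", -2),
                      planted_effect("M04", "both", "V1D7", -2)),
                    seed = 31)
  sim <- simulate_cohort(cfg)
  de <- de_analysis(sim$counts, sim$sample_info,
                    contrasts = list(hd = timepoint_contrast(
                      nested_design(sim$sample_info), "HD", "V1D7", "V1D0")))
  n_deg <- count_degs(de$results$hd)
  expect_gte(n_deg, 70)
  expect_lte(n_deg, 130)
})
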