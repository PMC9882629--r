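rand_vst <- function(n_genes = 40, n_samples = 12, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, 8, 1), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

test_that("eigengenes match a direct SVD oracle after sign-fixing", {
  v <- rand_vst(60, 14, seed = 19)
  sets <- lapply(1:10, function(i) sample(rownames(v), sample(5:15, 1)))
  names(sets) <- sprintf("M%02d", 1:10)
  gsc <- gene_set_collection(sets)
  eg <- compute_eigengenes(v, gsc, colnames(v))
  for (id in names(sets)) {
    M <- v[sets[[id]], ]
    sv <- svd(M - rowMeans(M))
    ref <- sv$v[, 1] * sv$d[1]
    r <- cor(ref, apply(M, 2, median))
    if (r < 0) ref <- -ref
    expect_equal(unname(eg$scores[id, ]), ref, tolerance = 1e-10)
    ## sign rule: correlation with the median member profile >= 0
    expect_gte(cor(eg$scores[id, ], apply(M, 2, median)), 0)
  }
})

test_that("rank-1 modules and negated matrices behave per the sign rule", {
  v <- rand_vst(10, 8, seed = 20)
  v[1:5, ] <- matrix(rep(v[1, ], each = 5), 5)   # identical member genes
  gsc <- gene_set_collection(list(R1 = rownames(v)[1:5],
                                  OTH = rownames(v)[6:10]))
  eg <- compute_eigengenes(v, gsc, colnames(v))
  cen <- v[1, ] - mean(v[1, ])
  expect_gt(abs(cor(eg$scores["R1", ], cen)), 1 - 1e-10)
  expect_gte(cor(eg$scores["R1", ], v[1, ]), 0)
  ## negating the matrix flips every eigengene
  eg2 <- compute_eigengenes(-v, gsc, colnames(v))
  expect_equal(eg2$scores, -eg$scores, tolerance = 1e-10)
})

test_that("eigengenes are invariant to gene order and permute with samples", {
  v <- rand_vst(30, 10, seed = 21)
  gsc1 <- gene_set_collection(list(A = rownames(v)[1:12]))
  gsc2 <- gene_set_collection(list(A = rev(rownames(v)[1:12])))
  e1 <- compute_eigengenes(v, gsc1, colnames(v))
  e2 <- compute_eigengenes(v, gsc2, colnames(v))
  expect_equal(e1$scores, e2$scores, tolerance = 1e-10)
  perm <- sample(colnames(v))
  e3 <- compute_eigengenes(v[, perm], gsc1, perm)
  expect_equal(e3$scores[, colnames(e1$scores), drop = FALSE], e1$scores,
               tolerance = 1e-10)
  ## single-member fallback: the centered gene itself
  gsc3 <- gene_set_collection(list(ONE = rownames(v)[5]))
  e4 <- compute_eigengenes(v, gsc3, colnames(v))
  expect_equal(unname(e4$scores["ONE", ]),
               unname(v[5, ] - mean(v[5, ])), tolerance = 1e-12)
})

test_that("delta eigengenes subtract pre from post and list exclusions", {
  scores <- matrix(c(0.2, 0.9, -0.1, 0.3), 1, 4,
                   dimnames = list("M01", c("p1_pre", "p1_post",
                                            "p2_pre", "p2_post")))
  eg <- structure(list(scores = scores), class = "eigengene_matrix")
  si <- data.frame(sample_id = colnames(scores),
                   subject_id = rep(c("p1", "p2"), each = 2),
                   timepoint = rep(c("pre", "post"), 2))
  d <- delta_eigengene(eg, si, "pre", "post")
  expect_equal(unname(d$delta[, "M01"]), c(0.7, 0.4))
  expect_length(d$excluded, 0)
  ## a subject missing the post sample is excluded and listed
  si2 <- si[-4, ]
  eg2 <- structure(list(scores = scores[, -4, drop = FALSE]),
                   class = "eigengene_matrix")
  d2 <- delta_eigengene(eg2, si2, "pre", "post")
  expect_identical(rownames(d2$delta), "p1")
  expect_identical(d2$excluded, "p2")
  ## pre == post gives exact zeros
  eg3 <- structure(list(scores = matrix(c(1, 1), 1, 2,
                        dimnames = list("M01", c("a_pre", "a_post")))),
                   class = "eigengene_matrix")
  si3 <- data.frame(sample_id = c("a_pre", "a_post"), subject_id = "a",
                    timepoint = c("pre", "post"))
  expect_equal(unname(delta_eigengene(eg3, si3, "pre", "post")$delta[, 1]), 0)
})

test_that("ferritin risk bands are inclusive at 200 and 1200", {
  expect_equal(ferritin_risk(838), "low")
  expect_equal(ferritin_risk(150), "high")
  expect_equal(ferritin_risk(c(200, 1200, 199.9, 1200.1)),
               c("low", "low", "high", "high"))
  expect_error(ferritin_risk(-1), "negative")
})

test_that("delta-eigengene titer models separate signal from orthogonal noise", {
  set.seed(22)
  n <- 40
  subj <- sprintf("p%02d", 1:n)
  delta <- matrix(rnorm(n * 3), n, 3, dimnames = list(subj, c("M1", "M2", "M3")))
  h <- setNames(rep(c(TRUE, FALSE), n / 2), subj)
  ## covid history fully determines the outcome; deltas orthogonal
  y <- setNames(2 * h + rnorm(n, 0, 1e-8), subj)
  m <- btm_titer_models(delta, y, h)
  expect_true(all(abs(m$slope) < 1e-6))
  ## a real slope on M2 is picked up with the others null
  y2 <- setNames(1.5 * delta[, "M2"] + 1.0 * h + rnorm(n, 0, 0.5), subj)
  m2 <- btm_titer_models(delta, y2, h)
  expect_lt(m2$fdr[m2$set_id == "M2"], 0.05)
  expect_lt(abs(m2$slope[m2$set_id == "M2"] - 1.5),
            2 * m2$se[m2$set_id == "M2"])
  ## FDR set membership does not depend on list order
  m3 <- btm_titer_models(delta, y2, h, enriched_ids = c("M3", "M1", "M2"))
  expect_setequal(m3$set_id[m3$fdr < 0.05], m2$set_id[m2$fdr < 0.05])
  expect_error(btm_titer_models(delta, y2, h, enriched_ids = "M9"),
               "not in delta")
})

test_that("baseline clinical medians, risk coding and models behave", {
  labs <- data.frame(
    subject_id = rep(c("p1", "p2"), each = 4),
    analyte = "ferritin",
    phase = rep(c("pre", "pre", "pre", "post_v1"), 2),
    days_after_vaccination = rep(c(NA, NA, NA, 10), 2),
    value = c(100, 150, 120, 140, 800, 900, 850, 1000))
  b <- baseline_clinical(labs)
  expect_equal(b$baseline, c(120, 850))
  expect_equal(b$n_values, c(3, 3))
  expect_equal(b$ferritin_risk, c("high", "low"))
  ## planted low-risk advantage is recovered with positive sign
  set.seed(23)
  n <- 40
  subj <- sprintf("p%02d", 1:n)
  fer <- c(rep(100, n / 2), rep(600, n / 2))
  bl <- data.frame(subject_id = subj, analyte = "ferritin",
                   baseline = fer, n_values = 3,
                   ferritin_risk = ferritin_risk(fer))
  h <- setNames(rep(c(TRUE, FALSE), n / 2), subj)
  y <- setNames(5 + 1.0 * (bl$ferritin_risk == "low") + rnorm(n, 0, 0.4),
                subj)
  ## a subject missing the M6 outcome only drops from that model
  y_m6 <- y; y_m6[1] <- NA
  res <- baseline_clinical_models(bl, list(v2d7 = y, m6 = y_m6), h,
                                  analytes = "ferritin")
  v2 <- res[res$outcome == "v2d7", ]
  m6 <- res[res$outcome == "m6", ]
  expect_lt(abs(v2$estimate - 1.0), 2 * v2$se)
  expect_lt(v2$p, 0.01)
  expect_equal(m6$n, v2$n - 1)
})

test_that("lab LFCs use natural log, reject non-positive values, and models recover", {
  labs <- data.frame(
    subject_id = rep("p1", 4), analyte = "wbc",
    phase = c("pre", "pre", "pre", "post_v1"),
    days_after_vaccination = c(NA, NA, NA, 12),
    value = c(5, 6, 7, 12))
  l <- lab_lfc(labs)
  expect_equal(l$lfc, log(12 / 6))
  ## doubling baseline and post leaves the LFC unchanged
  labs2 <- labs; labs2$value <- labs2$value * 2
  expect_equal(lab_lfc(labs2)$lfc, l$lfc)
  labs3 <- labs; labs3$value[4] <- 0
  expect_error(lab_lfc(labs3), "non-positive")
  ## planted slope recovery with covariates
  set.seed(24)
  n <- 40
  subj <- sprintf("p%02d", 1:n)
  lfcs <- data.frame(subject_id = subj, analyte = "wbc",
                     baseline = 5, post = 5 * exp(rnorm(n, 0, .4)))
  lfcs$lfc <- log(lfcs$post / lfcs$baseline)
  lfcs$days_after_vaccination <- sample(7:21, n, TRUE)
  h <- setNames(rep(c(TRUE, FALSE), n / 2), subj)
  y <- setNames(4 + 0.6 * lfcs$lfc + 0.8 * h + rnorm(n, 0, 0.3), subj)
  cov <- data.frame(covid_history = h, row.names = subj)
  res <- lfc_clinical_models(lfcs, list(v2d7 = y), cov, analytes = "wbc")
  expect_lt(abs(res$estimate - 0.6), 2 * res$se)
  ## constant predictor is skipped with a signal
  lfcs0 <- lfcs; lfcs0$lfc <- 0
  r0 <- lfc_clinical_models(lfcs0, list(v2d7 = y), cov, analytes = "wbc")
  expect_true(r0$skipped)
})
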