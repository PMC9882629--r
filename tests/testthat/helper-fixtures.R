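# Shared fixtures built in code: small paired designs and cohorts.

# a paired two-timepoint, two-group layout
paired_layout <- function(n_per_group = 6,
                          timepoints = c("V1D0", "V1D7")) {
  si <- expand.grid(timepoint = timepoints,
                    subject = seq_len(n_per_group),
                    group = c("HC", "HD"),
                    stringsAsFactors = FALSE)
  si$subject_id <- sprintf("%s%02d", si$group, si$subject)
  si$sample_id <- paste0(si$subject_id, "_", si$timepoint)
  si[, c("sample_id", "group", "subject_id", "timepoint")]
}

# NB counts for a given design with per-gene natural-log means
nb_counts <- function(si, n_genes, log_mean = 5, alpha = 0.1,
                      size_factors = NULL, seed = 1) {
  set.seed(seed)
  n <- nrow(si)
  sf <- size_factors %||% setNames(rep(1, n), si$sample_id)
  genes <- sprintf("g%04d", seq_len(n_genes))
  mu <- outer(exp(rnorm(n_genes, log_mean, 0.5)), sf[si$sample_id])
  cts <- matrix(rnbinom(n_genes * n, mu = mu, size = 1 / alpha),
                n_genes, n, dimnames = list(genes, si$sample_id))
  storage.mode(cts) <- "integer"
  cts
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a compact two-timepoint simulation config
small_sim_config <- function(seed, n_subjects = 6, n_genes = 400,
                             effects = list(planted_effect("M01", "both",
                                                           "V1D7", 1.5)),
                             ...) {
  sim_config(n_subjects_per_group = n_subjects, n_genes = n_genes,
             n_modules = 4, module_size_range = c(10, 20),
             timepoints = list(HC = c("V1D0", "V1D7"),
                               HD = c("V1D0", "V1D7")),
             planted_effects = effects, seed = seed, ...)
}

# hand-computed Kruskal-Wallis H with tie correction (independent of
# stats::kruskal.test)
oracle_kruskal_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
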