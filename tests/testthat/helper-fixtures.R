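# Shared fixtures, memoized so expensive cohorts are built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Small cohort for module-level tests.
small_cfg <- function(seed = 7, ...) {
  sim_config(n_studies = 3, samples_per_study = 6, n_genes = 500,
             cells_per_sample = 80, n_shared_pos_genes = 40,
             n_shared_neg_genes = 40, n_study_specific_age_genes = 10,
             n_marker_genes_per_class = 5, seed = seed, ...)
}

small_cohort <- function() {
  fixture("small_cohort", function() simulate_cohort(small_cfg()))
}

small_pbs <- function() {
  fixture("small_pbs", function() {
    lapply(small_cohort()$studies, function(s)
      pseudobulk(s$counts, s$cells, c("study", "sample_id", "broad_class")))
  })
}

small_obs <- function(mode = "log") {
  fixture(paste0("small_obs_", mode), function() {
    build_observations(small_pbs(),
                       rownames(small_cohort()$studies[[1]]$counts), mode)
  })
}

# Reference cohort used by the acceptance properties: 6 studies x 8 samples x
# 7 classes x 2000 genes, seed 101.
ref_cfg <- function() sim_config(seed = 101)

ref_cohort <- function() {
  fixture("ref_cohort", function() simulate_cohort(ref_cfg()))
}

ref_pbs <- function() {
  fixture("ref_pbs", function() {
    lapply(ref_cohort()$studies, function(s)
      pseudobulk(s$counts, s$cells, c("study", "sample_id", "broad_class")))
  })
}

ref_obs <- function(mode = "log") {
  fixture(paste0("ref_obs_", mode), function() {
    build_observations(ref_pbs(),
                       rownames(ref_cohort()$studies[[1]]$counts), mode)
  })
}

# Hand-built observation tables for clock tests.
make_obs <- function(expr, meta, mode = "log") {
  structure(list(expr = expr, meta = meta, mode = mode,
                 genes = colnames(expr)),
            class = "observation_table")
}

# Independent scalar-loop Pearson correlation oracle.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}

# Adjusted Rand index (closed-form contingency oracle).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
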