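#!/usr/bin/env Rscript
# PCA age models on per-sample pseudo-bulk: within each study the component
# most correlated with age predicts age well; projecting other studies onto
# that component transfers poorly because composition differs by study.

suppressPackageStartupMessages(library(ndclock))

if (!dir.exists("results/cohort/study1")) {
  stop("results/cohort/ not found; run analysis/01_simulate_cohort.R first")
}
cfg <- sim_config(seed = 101)
ids <- sprintf("study%d", seq_len(cfg$n_studies))
mats <- list()
ages <- list()
for (id in ids) {
  st <- read_study(file.path("results/cohort", id))
  pb <- suppressWarnings(pseudobulk(st$counts, st$cells,
                                    c("study", "sample_id")))
  mats[[id]] <- t(as.matrix(lognormalize(pb$counts)))
  ages[[id]] <- pb$meta$age_weeks
}

rows <- list()
for (s in ids) {
  m <- fit_pca_study(mats[[s]], ages[[s]])
  rows[[length(rows) + 1]] <- data.frame(
    train = s, target = s, component = m$component, r = m$r, p = m$p,
    mae = mean(abs(m$fitted - ages[[s]])))
  for (t in setdiff(ids, s)) {
    rep <- project_predict(m, mats[[t]], ages[[t]])
    rows[[length(rows) + 1]] <- data.frame(
      train = s, target = t, component = m$component, r = rep$r, p = NA,
      mae = rep$mae)
  }
}
out <- do.call(rbind, rows)
write.table(out, "results/pc_age.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
within <- out$mae[out$train == out$target]
cross <- out$mae[out$train != out$target]
cat(sprintf("PC age: median within %.2f wk, cross-projection %.2f wk\n",
            median(within), median(cross)))
cat("selected components:",
    paste(out$component[out$train == out$target], collapse = " "), "\n")
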