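#!/usr/bin/env Rscript
# Tissue-composition age models: study-specific elastic nets (within-study
# leave-one-sample-out error vs cross-study transfer error), the single/pair
# feature-selection grid, and the pooled astrocyte-progenitor meta-model.
# Expects results/cohort/ from 01_simulate_cohort.R.

suppressPackageStartupMessages(library(ndclock))

if (!dir.exists("results/cohort/study1")) {
  stop("results/cohort/ not found; run analysis/01_simulate_cohort.R first")
}
cfg <- sim_config(seed = 101)
ids <- sprintf("study%d", seq_len(cfg$n_studies))
studies <- lapply(setNames(ids, ids), function(id) {
  st <- read_study(file.path("results/cohort", id))
  comp <- composition(st$cells, classes = cfg$cell_classes)
  list(comp = comp, ages = comp$age_weeks)
})

fits <- lapply(studies, function(s) fit_study_model(s$comp, s$ages))
within <- vapply(fits, `[[`, numeric(1), "within_mae")
cross <- sapply(ids, function(a)
  mean(sapply(setdiff(ids, a), function(b)
    cross_apply(fits[[a]]$model, studies[[b]]$comp, studies[[b]]$ages)$mae)))
perf <- data.frame(study = ids, within_mae = within, cross_mae = cross)
write.table(perf, "results/composition_performance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("study-specific models: median within %.2f wk, cross %.2f wk (%.1fx)\n",
            median(within), median(cross), median(cross) / median(within)))

grid <- select_features(studies)
write.table(grid, "results/composition_feature_grid.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("best feature combination:", attr(grid, "best"), "\n")

meta <- fit_meta_model(studies)
write_model_json(meta, "results/meta_composition_model.json")
cat(sprintf("meta-model coefficients: astrocyte %+.2f, progenitor %+.2f\n",
            meta$coefficients[["Astrocyte"]],
            meta$coefficients[["Progenitor"]]))
meta_mae <- vapply(ids, function(ho) {
  m <- fit_meta_model(studies[setdiff(ids, ho)])
  cross_apply(m, studies[[ho]]$comp, studies[[ho]]$ages)$mae
}, numeric(1))
cat(sprintf("meta-model held-study MAE (median): %.2f wk\n", median(meta_mae)))
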