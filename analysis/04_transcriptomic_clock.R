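#!/usr/bin/env Rscript
# Cell-type-specific and cell-type-agnostic transcriptomic clocks on
# pseudo-bulk profiles (study x sample x class), with equal cell-type
# weighting, leave-study-out and leave-cell-type-out cross-validation, and a
# rank-normalized (depth-invariant) model variant.

suppressPackageStartupMessages(library(ndclock))

if (!dir.exists("results/cohort/study1")) {
  stop("results/cohort/ not found; run analysis/01_simulate_cohort.R first")
}
cfg <- sim_config(seed = 101)
ids <- sprintf("study%d", seq_len(cfg$n_studies))
pbs <- lapply(setNames(ids, ids), function(id) {
  st <- read_study(file.path("results/cohort", id))
  pseudobulk(st$counts, st$cells, c("study", "sample_id", "broad_class"))
})
universe <- intersect_genes(lapply(pbs, function(pb) rownames(pb$counts)))
obs <- build_observations(pbs, universe, "log")
w <- equal_weights(obs)
cat(sprintf("observation table: %d profiles x %d genes\n", nrow(obs$expr),
            length(universe)))

cv <- loso_cv(obs, w, seed = 101)
cc <- loco_cv(obs, w, seed = 101)
cat(sprintf("agnostic clock LOSO: MAE %.2f wk (median fold %.2f), r %.3f\n",
            cv$mae, median(cv$per_group$mae), cv$r))
cat(sprintf("agnostic clock LOCO: MAE %.2f wk, r %.3f\n", cc$mae, cc$r))
write.table(cv$rows, "results/clock_loso_predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cc$rows, "results/clock_loco_predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

model <- fit_clock(obs, w, seed = 101)
write_model_json(model, "results/clock_agnostic.json")
cat(sprintf("final model: %d nonzero genes (%d positive, %d negative)\n",
            length(model$coef), sum(model$coef > 0), sum(model$coef < 0)))

per_class <- fit_celltype_clocks(obs, seed = 101)
sizes <- vapply(per_class, function(m) length(m$coef), integer(1))
cat("per-class models fitted:", paste(names(per_class), sizes, sep = ":",
                                      collapse = " "), "\n")

rank_obs <- build_observations(pbs, universe, "rank")
rank_model <- fit_clock(rank_obs, equal_weights(rank_obs), seed = 101)
write_model_json(rank_model, "results/clock_rank.json")
rank_cv <- loso_cv(rank_obs, equal_weights(rank_obs), seed = 101)
cat(sprintf("rank-normalized variant LOSO: MAE %.2f wk, r %.3f\n",
            rank_cv$mae, rank_cv$r))
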