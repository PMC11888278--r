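#!/usr/bin/env Rscript
# Organoid and cross-species evaluation: predicts latent developmental age in
# an organoid-like cohort (compressed tempo, protocol offset) and a mouse-like
# cohort (ortholog-restricted genes, ~8x tempo), computes the similarity
# AUROC, per-tissue tempo slopes, and the compositional-vs-cell-autonomous
# synchrony ANOVA.

suppressPackageStartupMessages(library(ndclock))

if (!dir.exists("results/cohort/study1")) {
  stop("results/cohort/ not found; run analysis/01_simulate_cohort.R first")
}
cfg <- sim_config(seed = 101)
ids <- sprintf("study%d", seq_len(cfg$n_studies))
programs <- generate_programs(cfg)
pbs <- lapply(setNames(ids, ids), function(id) {
  st <- read_study(file.path("results/cohort", id))
  pseudobulk(st$counts, st$cells, c("study", "sample_id", "broad_class"))
})
universe <- intersect_genes(lapply(pbs, function(pb) rownames(pb$counts)))
obs <- build_observations(pbs, universe, "log")
model <- read_model_json("results/clock_agnostic.json")
meta_comp <- read_model_json("results/meta_composition_model.json")

## organoid cohort: tempo 0.55, 5-week protocol offset
org <- simulate_organoid_cohort(cfg, programs, tempo = 0.55,
                                offset_weeks = 5, seed = 118)
pb_o <- pseudobulk(org$counts, org$cells,
                   c("study", "sample_id", "broad_class"), min_cells = 10)
obs_o <- build_observations(list(pb_o), universe, "log")
pred_o <- predict(model, obs_o)
cat(sprintf("organoid: r(predicted, latent age) = %.3f over %d profiles\n",
            cor(pred_o, obs_o$meta$age_weeks), length(pred_o)))
a_sim <- similarity_auroc(obs_o$expr, pred_o, threshold_weeks = 5,
                          scope = "within_class",
                          classes = obs_o$meta$cell_class)
cat(sprintf("organoid similarity AUROC (5 wk, within class): %.3f\n", a_sim))

## mouse cohort: 85%% one-to-one orthologs, tempo 8
mouse <- simulate_cross_species_cohort(cfg, programs, ortholog_fraction = 0.85,
                                       tempo = 8, seed = 130)
pb_m <- pseudobulk(mouse$counts, mouse$cells,
                   c("study", "sample_id", "broad_class"))
obs_m <- restrict_orthologs(
  build_observations(list(pb_m), rownames(mouse$counts), "log"),
  mouse$ortholog_map)
obs_h <- restrict_orthologs(obs, mouse$ortholog_map)
clock_r <- fit_clock(obs_h, equal_weights(obs_h), seed = 101)
pred_m <- predict(clock_r, obs_m)
cat(sprintf("mouse: %d ortholog genes, r(predicted, latent) = %.3f\n",
            length(obs_m$genes), cor(pred_m, obs_m$meta$age_weeks)))

## tempo slopes across tissues (native axes in weeks)
cv_h <- loso_cv(obs_h, equal_weights(obs_h), seed = 101)
df <- rbind(
  data.frame(tissue = "human", time = cv_h$rows$true,
             predicted = cv_h$rows$pred),
  data.frame(tissue = "organoid",
             time = obs_o$meta$culture_age_days / 7, predicted = pred_o),
  data.frame(tissue = "mouse", time = pb_m$meta$embryonic_day / 7,
             predicted = pred_m))
ts <- tempo_slopes(df)
cat("tempo slopes (predicted weeks per native week):\n")
print(round(ts$slopes, 3))
cat(sprintf("tissue effect: F = %.1f (p = %.3g)\n",
            ts$anova$F[ts$anova$term == "tissue"],
            ts$anova$p[ts$anova$term == "tissue"]))
write.table(df, "results/tempo_predictions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## synchrony: compositional age vs cell-autonomous age across tissues
comp_h <- do.call(rbind, lapply(ids, function(id) {
  st <- read_study(file.path("results/cohort", id))
  composition(st$cells, classes = cfg$cell_classes)
}))
comp_o <- composition(org$cells, classes = cfg$cell_classes)
comp_m <- composition(mouse$cells, classes = cfg$cell_classes)
sample_pred <- function(rows, preds) {
  tapply(preds, rows$sample_id, mean)
}
sync <- rbind(
  data.frame(tissue = "human",
             time = predict(meta_comp, comp_h),
             predicted = as.numeric(sample_pred(cv_h$rows, cv_h$rows$pred)[
               comp_h$sample_id])),
  data.frame(tissue = "organoid",
             time = predict(meta_comp, comp_o),
             predicted = as.numeric(tapply(pred_o, obs_o$meta$sample_id,
                                           mean)[comp_o$sample_id])),
  data.frame(tissue = "mouse",
             time = predict(meta_comp, comp_m),
             predicted = as.numeric(tapply(pred_m, obs_m$meta$sample_id,
                                           mean)[comp_m$sample_id])))
sync <- sync[complete.cases(sync), ]
st2 <- tempo_slopes(sync)
cat(sprintf("synchrony (cell-autonomous ~ compositional age x tissue): interaction F = %.2f (p = %.3g)\n",
            st2$anova$F[st2$anova$term == "time:tissue"],
            st2$anova$p[st2$anova$term == "time:tissue"]))
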