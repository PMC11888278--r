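#!/usr/bin/env Rscript
# Study-specific age-correlated genes, aggregate rank-standardized
# co-expression over the clock's gene programs, module clustering, enrichment
# of study age genes in modules, and the sign-classification AUROC relating
# model coefficients to per-study age correlations.

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
model <- read_model_json("results/clock_agnostic.json")

tabs <- age_genes_by_study(obs)
age_sets <- lapply(tabs, function(t) t$gene[t$significant])
cat("significant age genes per study:",
    paste(names(age_sets), lengths(age_sets), sep = ":", collapse = " "), "\n")

aur <- sign_classification_auroc(model, tabs, mode = "signed")
aur_abs <- sign_classification_auroc(model, tabs, mode = "absolute")
cat(sprintf("sign-classification AUROC: signed %.3f, |r| contrast %.3f\n",
            mean(aur), mean(aur_abs)))

# aggregate network over the model's nonzero genes
genes <- names(model$coef)
nets <- lapply(ids, function(s)
  study_network(obs$expr[obs$meta$study == s, , drop = FALSE], genes))
agg <- aggregate_network(nets)
hc <- hclust(dist(agg$matrix), method = "complete")
cut_h <- mean(sort(hc$height, decreasing = TRUE)[1:2])
agg <- cluster_modules(agg, cut_h)
cat(sprintf("aggregate network: %d genes, cut at %.2f -> %d modules (sizes %s)\n",
            length(agg$genes), cut_h, length(unique(agg$modules)),
            paste(table(agg$modules), collapse = " ")))
write.table(data.frame(gene = names(agg$modules), module = agg$modules),
            "results/coexpression_modules.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

enr <- module_enrichment(agg, age_sets, universe)
write.table(enr, "results/module_age_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("module x study enrichments with FDR < 0.05: %d / %d\n",
            sum(enr$p_adj < 0.05), nrow(enr)))
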