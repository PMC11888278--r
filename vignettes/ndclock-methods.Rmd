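---
title: "Methods: compositional and transcriptomic clocks for neurodevelopmental age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional and transcriptomic clocks for neurodevelopmental age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ndclock estimates the developmental age of brain tissue samples and of
individual cell classes, in gestational weeks, from single-cell RNA-seq
pooled across heterogeneous studies. Two signals are modeled separately
because they generalize very differently across datasets: tissue-level
composition (which cell classes are present, in what proportions) and
cell-autonomous transcriptomic maturation (how each class's own expression
changes with age). This vignette documents the models, the parameters that
matter, the synthetic cohort generator the package is validated on, and the
numerical choices that were genuinely open.

## Pseudo-bulk substrate and normalization

All models operate on pseudo-bulk profiles: raw counts summed over the cells
of one group, by default one (study, sample, broad class) triple
(`pseudobulk()`). Aggregation always precedes normalization — the aggregate
is treated as a bulk-like library and normalized as a whole. Two
normalizations are supported:

* **Log normalization** (`lognormalize()`): each entry $c$ of a profile with
  total $T$ becomes $\ln(1 + s\,c/T)$ with scale factor $s = 10^4$. The size
  factor is the aggregate's own total, not the mean of its member cells'
  totals; the two differ only by a constant inside the log at fixed
  composition, and the aggregate total is the natural library size of the
  aggregated profile.
* **Rank normalization** (`rank_normalize()`): within a profile every count
  is replaced by its average rank among all genes divided by the number of
  genes, giving values in $(0,1]$. Ties (including the zero block) take the
  average rank — this is what makes the transform invariant to *any*
  strictly increasing per-profile transform, hence to sequencing depth,
  which is the point of the variant. Rank values depend on the gene universe
  they are computed over, so the universe is fixed (by intersection across
  datasets, `intersect_genes()`) *before* normalization; subsetting genes
  after ranking is deliberately not equivalent and not supported.

Author cell-type labels are harmonized into seven broad classes (astrocyte,
progenitor, excitatory neuron, inhibitory neuron, oligodendrocyte, immune,
vascular) plus `Other` via a user-supplied map (`harmonize()`). Consensus
markers per class (`recurrent_markers()`) use a one-vs-rest
log2 fold change $\log_2\!\big((\bar x_{in}+1)/(\bar x_{out}+1)\big) > 2$
and in-class expressing fraction $> 0.2$, required in every sample: the
pseudocount-stabilized contrast is monotone in the underlying fold change
and avoids division by zero for off genes.

## Compositional age models

Per-sample class proportions (`composition()`) feed three models:

* **Study-specific elastic nets** (`fit_study_model()`): age is regressed on
  all class proportions with alpha in $\{0.1, \dots, 1\}$ and a 50-point
  log-spaced lambda path, selected by leave-one-sample-out MAE. Studies need
  at least four distinct time points. The lambda path is built explicitly
  down to $10^{-6}\,\lambda_{max}$ because the solver's automatic path stops
  once deviance saturates, which leaves visible shrinkage bias on
  near-noiseless studies.
* **Feature selection** (`select_features()`): every single class and
  unordered pair is scored by leave-study-out OLS MAE. Pairs only — the
  search is intentionally small and interpretable.
* **Meta-analytic model** (`fit_meta_model()`): pooled OLS of age on
  astrocyte and progenitor proportions across training studies. Proportions
  enter unscaled on $[0,1]$, so coefficients read directly as
  weeks-per-unit-proportion; the expected sign structure is
  astrocyte-positive (gliogenesis rises through development) and
  progenitor-negative (the progenitor pool is depleted).

Predictions are raw regression output, never clipped to positive ages.

## PCA age models

`fit_pca_study()` runs PCA (gene-centered, no variance scaling) on per-sample
log-normalized pseudo-bulk, selects the component with the largest |Pearson
r| against age among the first five, and stores a univariate OLS of age on
that score. Significance of the correlation is the usual t-test at p < 0.05.
Cross-study projection (`project_predict()`) centers the target with the
*training* study's gene means — a projection must not peek at target
statistics — and imputes genes missing from the target at the training mean
(zero after centering); below 50% gene overlap it refuses to predict.

## The transcriptomic clock

The core predictor (`fit_clock()`) is a weighted elastic net of age on
normalized pseudo-bulk expression over the common gene universe, trained
jointly on all cell classes. Two design choices carry the cross-study logic:

* **Equal cell-type weighting** (`equal_weights()`): observation $i$ in
  study $s$, class $c$ receives weight $N/(S\,k_s\,m_{sc})$, where $S$ is
  the number of studies, $k_s$ the classes in study $s$ and $m_{sc}$ the
  profiles of class $c$ in study $s$. Every class contributes equally within
  its study and every study contributes equally overall; weights sum to $N$
  so the penalty scale stays comparable to the unweighted case. Weighting is
  implemented as observation weights rather than resampling — deterministic
  and exact.
* **Study-grouped hyperparameter CV**: alpha and lambda are chosen by
  cross-validation whose folds are whole studies, minimizing weighted MAE.
  Random folds would place profiles of the same study on both sides and
  reward memorizing study identity, which is precisely the failure mode the
  cross-study evaluation is designed to expose. Because folds are
  deterministic given the grouping, fitting is fully reproducible; the seed
  argument exists for interface stability only.

The default alpha grid is $\{0.1, 0.5, 1\}$ with a 50-point lambda path —
coarse on purpose: with study-grouped folds the CV surface is flat in alpha,
and a dense grid multiplies runtime without changing the selected model
class. Both are configurable. Model selection uses MAE, the unit the
package reports everywhere (weeks); RMSE selection is a one-line change.

Evaluation schemes: `loso_cv()` (leave-study-out) and `loco_cv()`
(leave-cell-type-out) refit the full pipeline per fold, recomputing equal
weights on the training subset, and predict each held-out observation
exactly once. Held-out ages are never read during fitting, which the test
suite asserts at bit level by permuting held-out labels. Per-class clocks
(`fit_celltype_clocks()`) restrict rows to one class; classes observed in
fewer than two studies are skipped.

At prediction time (`predict()` on a `clock_model`) missing model genes are
a hard error by default; `allow_missing` imputes at most 20% of model genes
at zero. Silent imputation beyond that would mask genuine universe
mismatches such as an ortholog-restricted universe applied to the wrong
namespace. Cross-species prediction goes through `restrict_orthologs()`,
which enforces a strictly one-to-one map, reduces the universe to mapped
genes, and renames foreign profiles into the reference namespace.

## Co-expression modules and gene screens

Per study, gene-gene Spearman correlations over that study's pseudo-bulk
rows are rank-standardized (`study_network()`): the upper-triangle
correlations are jointly ranked (ascending, average ties, diagonal
excluded) and divided by the maximum rank. Ranking the upper triangle
rather than the full symmetric matrix is equivalent up to ties and avoids
counting every pair twice. Standardized networks are averaged across
studies (`aggregate_network()`) and clustered (`cluster_modules()`) with
Euclidean distance on network rows and complete linkage — the cited
tooling's defaults, since nothing in the method constrains the linkage —
cut at a user height (module ids ordered by size). Cut heights are
data-scale dependent; the analysis drivers derive one from the top of the
dendrogram when they need exactly two modules.

Study age genes (`age_genes()`) are per-gene Pearson correlations with age,
t-test p-values, and within-study BH-FDR at 0.05; constant genes are
excluded from the adjustment rather than diluting it. Enrichment of age
genes in modules uses one-sided Fisher tests ("enrichment" is directional)
with BH across the full module-by-study grid; gene-set-in-module enrichment
uses the upper-tail hypergeometric with a 10-200 in-universe size window.
The gene-set screen (`screen_genesets()`) refits the clock restricted to
each set (50-500 in-universe genes by default, sizes counted *after*
intersection with the analysis universe) under the same deterministic
leave-study-out folds for every set, so differences between sets cannot
come from fold noise; `empirical_pvalue()` uses the $(k+1)/(n+1)$
convention and never returns exactly zero.

## Evaluation statistics

`similarity_auroc()` computes all pairwise Spearman correlations between
whole profiles, splits pairs at an age-difference threshold (default 3
weeks), and reports the tie-corrected Mann-Whitney AUROC — the probability
that a similar-age pair is more correlated than a different-age pair. The
U/(n1 n2) form is used because it lands on the standard [0,1] scale; the
average-rank formulation is a linear transform of it. `group_shift()` is a
two-sided Wilcoxon rank-sum with the mean difference in weeks.
`tempo_slopes()` fits per-tissue OLS slopes of predicted age against each
tissue's native time axis and an ANOVA of `predicted ~ time * tissue`; all
native axes are converted to weeks (culture days / 7, embryonic days / 7) so
slopes are week-per-week and ratios are unit-free.

## The synthetic cohort generator

`simulate_cohort()` generates the multi-study data every stage is validated
on. What it emulates, per study: donor samples on a jittered age grid over
5-40 gestational weeks (at least four distinct time points, mirroring the
modeling requirement); seven broad classes whose expected proportions follow
a softmax over linear logit scores, with the rising-class slope strictly
maximal (astrocyte) and the declining-class slope strictly minimal
(progenitor), which guarantees strictly monotone expected trajectories on
the simplex; per-study logit offsets on those trajectories (s.d. 1.0),
shrunk by a factor 0.2 for astrocytes and progenitors whose trajectories
are conserved across studies — the structure that makes study-specific
composition fail to transfer while the astro/progenitor signal generalizes;
shared positive and negative age programs (100 genes each, ±0.05 natural-log
units per week, i.e. ~5.8-fold across the age range) expressed in every
class; 30 study-specific age genes per study; 10 canonical markers per class
(baseline −2, in-class boost +6 log units — strong on/off markers occupying
~14% of the in-class library); per-study per-gene batch offsets (s.d. 0.3);
and Gamma-Poisson counts (shared dispersion 0.5) with log-normal library
sizes (mean 2500, s.d. 0.35). The composition-offset scale was set so that
study-specific compositional models lose accuracy severalfold across
studies, the qualitative regime reported for real multi-study fetal-brain
compilations; with intercept-only offsets the inflation is ~2-6x, smaller
than the ~8x seen in real data, because real studies also differ in
trajectory shape — a known limitation.

All randomness flows from one seed through per-study child seeds, so a fixed
seed gives byte-identical cohorts. Organoid-like cohorts map latent
transcriptomic age affinely onto culture time
(latent = offset + tempo x culture weeks; tempo 1 with zero offset
reproduces the gestational generator bit-for-bit under the same seed).
Mouse-like cohorts set latent age to tempo x embryonic day / 7 over
E10.5-E18.5 and rename a random fraction of genes through a generated
one-to-one ortholog map.

What the generator does *not* emulate: doublets, ambient RNA, UMI
saturation, per-cell-type dispersion differences, trajectory-shape
differences between studies, or realistic marginal count distributions
beyond NB with library-size variation. Passing tests on this cohort
therefore demonstrate the estimators' correctness and their qualitative
cross-study behavior, not performance on real atlases.

## Problem sizes and numerical notes

The reference cohort used by the test suite and the acceptance script is 6
studies x 8 samples x 7 classes x 2000 genes with 150 cells per sample
(~7200 cells), chosen so the full pipeline — simulation, two normalizations,
all cross-validation loops, networks, screens — runs end to end in well
under a minute each; the null-calibration cohort is smaller (4 studies, 800
genes). Degenerate inputs are handled explicitly: a constant age target
returns an intercept-only clock; an all-constant composition table returns
the training-mean predictor; constant genes are dropped from networks and
excluded from FDR; zero-total profiles are an error unless explicitly
dropped. Model JSON serialization writes 17 significant digits and stores
named vectors as objects, so models round-trip exactly.

```{r example}
library(ndclock)
cfg <- sim_config(seed = 101)
cohort <- simulate_cohort(cfg)
pbs <- lapply(cohort$studies, function(s)
  pseudobulk(s$counts, s$cells, c("study", "sample_id", "broad_class")))
obs <- build_observations(pbs, rownames(cohort$studies[[1]]$counts), "log")
cv <- loso_cv(obs, equal_weights(obs))
cv$mae  # leave-study-out error in weeks
```
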