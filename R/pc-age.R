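#' Fit a within-study PCA age model on per-sample pseudo-bulk
#'
#' PCA (gene-centered, no scaling) of the per-sample log-normalized
#' pseudo-bulk matrix; the component most strongly Pearson-correlated with
#' age is selected and a univariate OLS of age on its score is stored.
#' Significance of the PC-age correlation is the t-test of Pearson r.
#'
#' @param pb Samples x genes matrix of log-normalized pseudo-bulk expression.
#' @param ages Sample ages (weeks); must not be constant.
#' @param n_components Components to compute (default 5, capped by rank).
#' @return List of class `"pc_model"`: `gene_means`, `loading` (unit norm),
#'   `component`, `slope`, `intercept`, `r`, `p`, `fitted` (training
#'   predictions), `n_components`.
#' @export
fit_pca_study <- function(pb, ages, n_components = 5) {
  stopifnot(nrow(pb) == length(ages))
  if (length(unique(ages)) < 2L) stop("ages are constant; correlation undefined")
  if (nrow(pb) < 4L) stop("at least 4 samples required")
  k <- min(n_components, nrow(pb) - 1L, ncol(pb))
  pc <- stats::prcomp(pb, center = TRUE, scale. = FALSE, rank. = k)
  cors <- apply(pc$x[, seq_len(k), drop = FALSE], 2,
                function(s) safe_cor(s, ages))
  cors[is.na(cors)] <- 0
  sel <- which.max(abs(cors))
  score <- pc$x[, sel]
  fit <- stats::lm(ages ~ score)
  ct <- stats::cor.test(score, ages)
  structure(list(
    gene_means = pc$center,
    loading = pc$rotation[, sel],
    component = unname(sel),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = unname(cors[sel]),
    p = ct$p.value,
    significant = ct$p.value < 0.05,
    fitted = unname(stats::fitted(fit)),
    n_components = k), class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model: PC%d selected (r = %.3f, p = %.3g), %d genes\n",
              x$component, x$r, x$p, length(x$loading)))
  invisible(x)
}

#' Project new samples onto a study's age-correlated PC and predict age
#'
#' Scores use the TRAINING study's gene means (no peeking at target
#' statistics); target genes missing from the model contribute 0 after
#' centering (imputed at the training mean). Less than 50% gene overlap is an
#' error.
#'
#' @param model A `"pc_model"`.
#' @param pb Samples x genes matrix (log-normalized pseudo-bulk).
#' @param ages True ages (weeks).
#' @return An `"eval_report"` with a `scores` element added.
#' @export
project_predict <- function(model, pb, ages) {
  genes <- names(model$loading)
  common <- intersect(genes, colnames(pb))
  if (length(common) < 0.5 * length(genes)) {
    stop(sprintf("only %d/%d model genes present (<50%% overlap)",
                 length(common), length(genes)))
  }
  centered <- matrix(0, nrow(pb), length(genes),
                     dimnames = list(rownames(pb), genes))
  centered[, common] <- sweep(pb[, common, drop = FALSE], 2,
                              model$gene_means[common], "-")
  scores <- as.vector(centered %*% model$loading)
  preds <- model$intercept + model$slope * scores
  rep <- summarize_predictions(preds, ages)
  rep$scores <- scores
  rep
}
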