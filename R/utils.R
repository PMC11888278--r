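#' Area under the ROC curve via the Mann-Whitney U statistic
#'
#' Computes AUROC = U / (n1 * n0) with average ranks, so tied scores receive
#' half credit. This is the probability that a randomly chosen positive scores
#' higher than a randomly chosen negative.
#'
#' @param scores Numeric vector of scores (higher = more positive-like).
#' @param labels Logical vector, `TRUE` for the positive class.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("auroc needs at least one observation in each class")
  }
  r <- rank(scores, ties.method = "average")
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Empirical (permutation-style) p-value for a lower-is-better score
#'
#' Uses the +1 convention so the p-value is never exactly zero:
#' p = (#\{null <= observed\} + 1) / (n + 1).
#'
#' @param observed Observed score (lower is better, e.g. a MAE).
#' @param null_scores Numeric vector of null scores.
#' @return p-value in \[1/(n+1), 1\].
#' @export
empirical_pvalue <- function(observed, null_scores) {
  stopifnot(length(observed) == 1L, is.finite(observed))
  null_scores <- null_scores[is.finite(null_scores)]
  if (length(null_scores) == 0L) stop("null_scores must be non-empty")
  (sum(null_scores <= observed) + 1) / (length(null_scores) + 1)
}

# Pearson r that returns NA (instead of erroring) for constant vectors.
safe_cor <- function(x, y, method = "pearson") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

# Deterministic child seeds derived from a parent seed (kept < 2^31).
child_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run expr with a local RNG state seeded at `seed`, restoring global state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  expr
}
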