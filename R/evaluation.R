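#' Summarize predictions against true ages
#'
#' @param preds,truth Numeric vectors of equal length (weeks).
#' @param groups Optional data.frame of per-observation metadata carried into
#'   the row table.
#' @param by Optional column name in `groups` to compute per-group MAE and
#'   Pearson r over (defaults to `"study"` when present).
#' @return List of class `"eval_report"`: `rows` (per-observation table with
#'   `pred`, `true`, `abs_err`), `mae`, `r` (NA when either vector is
#'   constant), and `per_group` when `by` applies.
#' @export
summarize_predictions <- function(preds, truth, groups = NULL, by = NULL) {
  if (length(preds) != length(truth)) {
    stop("preds and truth have different lengths")
  }
  stopifnot(length(preds) >= 1L)
  rows <- data.frame(pred = as.numeric(preds), true = as.numeric(truth))
  rows$abs_err <- abs(rows$pred - rows$true)
  if (!is.null(groups)) rows <- cbind(rows, groups)
  if (is.null(by) && !is.null(groups) && "study" %in% names(groups)) {
    by <- "study"
  }
  rep <- list(rows = rows,
              mae = mean(rows$abs_err),
              r = safe_cor(rows$pred, rows$true))
  if (!is.null(by) && by %in% names(rows)) {
    per <- lapply(split(rows, rows[[by]]), function(d) {
      data.frame(group = d[[by]][1], n = nrow(d), mae = mean(d$abs_err),
                 r = safe_cor(d$pred, d$true), stringsAsFactors = FALSE)
    })
    rep$per_group <- do.call(rbind, c(per, make.row.names = FALSE))
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n = %d, MAE = %.3f weeks, r = %.3f\n",
              nrow(x$rows), x$mae, x$r))
  invisible(x)
}

#' Age-similarity AUROC over profile pairs
#'
#' Computes all pairwise Spearman correlations between whole expression
#' profiles, splits pairs into similar-age (|delta age| < threshold) and
#' different-age pairs, and reports the probability that a similar-age pair is
#' more correlated than a different-age pair (Mann-Whitney AUROC, ties half
#' credit).
#'
#' @param expr Profiles x genes matrix.
#' @param ages Per-profile ages (predicted or observed), weeks.
#' @param threshold_weeks Age-difference threshold (default 3).
#' @param scope `"all"`, `"within_class"` (only same-class pairs) or
#'   `"across_class"` (only different-class pairs).
#' @param classes Per-profile class labels (required unless scope = "all").
#' @return AUROC in \[0, 1\].
#' @export
similarity_auroc <- function(expr, ages, threshold_weeks = 3,
                             scope = c("all", "within_class", "across_class"),
                             classes = NULL) {
  scope <- match.arg(scope)
  n <- nrow(expr)
  stopifnot(length(ages) == n)
  if (scope != "all" && is.null(classes)) {
    stop("classes required for scope = ", scope)
  }
  cors <- stats::cor(t(expr), method = "spearman")
  pr <- which(upper.tri(cors), arr.ind = TRUE)
  if (scope == "within_class") {
    pr <- pr[classes[pr[, 1]] == classes[pr[, 2]], , drop = FALSE]
  } else if (scope == "across_class") {
    pr <- pr[classes[pr[, 1]] != classes[pr[, 2]], , drop = FALSE]
  }
  if (nrow(pr) < 2L) stop("fewer than 2 profile pairs in scope")
  dage <- abs(ages[pr[, 1]] - ages[pr[, 2]])
  similar <- dage < threshold_weeks
  if (all(similar) || !any(similar)) {
    stop("threshold ", threshold_weeks,
         " weeks leaves no contrast between similar and different pairs")
  }
  auroc(cors[pr], similar)
}

#' Mean age shift between two groups of predictions
#'
#' @param preds_a,preds_b Numeric vectors of predicted ages (weeks).
#' @return List: `delta_weeks` (mean(a) - mean(b)) and `p` (two-sided
#'   Wilcoxon rank-sum; exact for small tie-free samples, normal
#'   approximation with tie correction otherwise).
#' @export
group_shift <- function(preds_a, preds_b) {
  if (length(preds_a) == 0L || length(preds_b) == 0L) {
    stop("both groups must be non-empty")
  }
  wt <- suppressWarnings(stats::wilcox.test(preds_a, preds_b))
  list(delta_weeks = mean(preds_a) - mean(preds_b), p = wt$p.value)
}

#' Developmental tempo slopes and tissue ANOVA
#'
#' Per tissue, the OLS slope of predicted age against that tissue's native
#' time axis (weeks per week when both axes are in weeks). The ANOVA table of
#' `predicted ~ time * tissue` carries the tissue main effect and the
#' time-by-tissue interaction; with `time` set to compositional age this is
#' the compositional-vs-cell-autonomous synchrony test.
#'
#' @param df Data.frame with columns `tissue`, `time` (native axis) and
#'   `predicted` (weeks).
#' @return List: `slopes` (named per-tissue), `intercepts`, `anova`
#'   (data.frame with term, F, p).
#' @export
tempo_slopes <- function(df) {
  stopifnot(all(c("tissue", "time", "predicted") %in% names(df)))
  tissues <- unique(df$tissue)
  if (length(tissues) < 2L) stop("at least 2 tissues required")
  slopes <- intercepts <- stats::setNames(numeric(length(tissues)), tissues)
  for (ts in tissues) {
    d <- df[df$tissue == ts, ]
    if (nrow(d) < 3L) stop("tissue ", ts, " has fewer than 3 points")
    if (stats::sd(d$time) == 0) stop("tissue ", ts, " has constant native time")
    fit <- stats::lm(predicted ~ time, data = d)
    slopes[ts] <- stats::coef(fit)[2]
    intercepts[ts] <- stats::coef(fit)[1]
  }
  df$tissue <- factor(df$tissue)
  av <- stats::anova(stats::lm(predicted ~ time * tissue, data = df))
  anova_tab <- data.frame(term = rownames(av), df = av$Df, F = av$`F value`,
                          p = av$`Pr(>F)`, stringsAsFactors = FALSE)
  list(slopes = slopes, intercepts = intercepts, anova = anova_tab)
}
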