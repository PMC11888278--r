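#' Build the observation table for clock training
#'
#' One row per pseudo-bulk profile (study x sample x cell class), normalized
#' over a fixed, pre-intersected gene universe. Log mode applies
#' [lognormalize()] to each aggregate; rank mode ranks genes within each
#' aggregate profile ([rank_normalize()]), making rows depth-invariant.
#'
#' @param pbs List of `"pseudobulk_table"` objects (one per dataset), each
#'   with `age_weeks` in its metadata.
#' @param universe Character vector, the common gene universe; every dataset
#'   must contain all of it.
#' @param mode `"log"` or `"rank"`.
#' @return List of class `"observation_table"`: `expr` (observations x genes),
#'   `meta` (study, sample_id, cell_class, age_weeks, n_cells), `mode`,
#'   `genes`.
#' @export
build_observations <- function(pbs, universe, mode = c("log", "rank")) {
  mode <- match.arg(mode)
  if (inherits(pbs, "pseudobulk_table")) pbs <- list(pbs)
  blocks <- lapply(pbs, function(pb) {
    missing <- setdiff(universe, rownames(pb$counts))
    if (length(missing)) {
      stop("genes absent from a dataset (universe must be pre-intersected): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    if (any(is.na(pb$meta$age_weeks))) {
      stop("pseudobulk rows without age metadata")
    }
    counts <- pb$counts[universe, , drop = FALSE]
    norm <- switch(mode,
                   log = lognormalize(counts),
                   rank = rank_normalize(counts))
    expr <- t(as.matrix(norm))
    meta <- pb$meta
    if (is.null(meta$cell_class) && !is.null(meta$broad_class)) {
      meta$cell_class <- meta$broad_class
    }
    list(expr = expr, meta = meta)
  })
  expr <- do.call(rbind, lapply(blocks, `[[`, "expr"))
  meta_cols <- Reduce(intersect, lapply(blocks, function(b) names(b$meta)))
  meta <- do.call(rbind, lapply(blocks, function(b)
    b$meta[, meta_cols, drop = FALSE]))
  rownames(meta) <- NULL
  rownames(expr) <- NULL
  structure(list(expr = expr, meta = meta, mode = mode, genes = universe),
            class = "observation_table")
}

#' @export
print.observation_table <- function(x, ...) {
  cat(sprintf("observation_table (%s): %d profiles x %d genes, %d studies\n",
              x$mode, nrow(x$expr), length(x$genes),
              length(unique(x$meta$study))))
  invisible(x)
}

#' Subset an observation table by row index
#'
#' @param obs An `"observation_table"`.
#' @param idx Integer or logical row index.
#' @return The subsetted `"observation_table"` (same universe and mode).
#' @export
subset_obs <- function(obs, idx) {
  structure(list(expr = obs$expr[idx, , drop = FALSE],
                 meta = obs$meta[idx, , drop = FALSE],
                 mode = obs$mode, genes = obs$genes),
            class = "observation_table")
}

#' Equal cell-type weights within each study
#'
#' Observation i in study s, class c (m_sc observations of that class in the
#' study, k_s classes in the study, S studies, N observations overall) gets
#' weight N / (S * k_s * m_sc): within each study every class carries equal
#' total weight, every study carries equal total weight, and weights sum to N.
#'
#' @param obs An `"observation_table"`.
#' @return Numeric weight vector, one per observation.
#' @export
equal_weights <- function(obs) {
  meta <- obs$meta
  n <- nrow(meta)
  s_total <- length(unique(meta$study))
  k_s <- tapply(meta$cell_class, meta$study,
                function(x) length(unique(x)))
  m_sc <- table(meta$study, meta$cell_class)
  w <- n / (s_total * k_s[meta$study] *
              m_sc[cbind(meta$study, meta$cell_class)])
  unname(as.numeric(w))
}

#' Fit a sparse transcriptomic age clock (weighted elastic net)
#'
#' Trains a weighted elastic-net regression of age on normalized expression,
#' selecting alpha and lambda by cross-validation grouped by study (never by
#' random folds, so study identity cannot leak into hyperparameter choice),
#' minimizing weighted MAE.
#'
#' @param obs An `"observation_table"`.
#' @param weights Observation weights (e.g. [equal_weights()]); default all 1.
#' @param alphas Elastic-net mixing grid (default `c(0.1, 0.5, 1)`).
#' @param nlambda Lambda path length per alpha.
#' @param lambda Optional fixed lambda: skips the CV search and fits at
#'   (`alphas[1]`, `lambda`).
#' @param cv_groups `"study"` (default; errors if only one study) or
#'   `"sample"` (leave-sample-out grouping, for single-study fits).
#' @param seed Integer; kept for interface stability (folds are deterministic
#'   given the grouping, so fitting is reproducible regardless).
#' @return List of class `"clock_model"`: `mode`, `genes` (universe),
#'   `coef` (named nonzero coefficients), `intercept`, `alpha`, `lambda`,
#'   `cv_mae`, `provenance`.
#' @export
fit_clock <- function(obs, weights = NULL, alphas = c(0.1, 0.5, 1),
                      nlambda = 50, lambda = NULL,
                      cv_groups = c("study", "sample"), seed = 1L) {
  cv_groups <- match.arg(cv_groups)
  x <- obs$expr
  y <- obs$meta$age_weeks
  if (is.null(weights)) weights <- rep(1, nrow(x))
  stopifnot(length(weights) == nrow(x), all(weights > 0))
  if (stats::sd(y) == 0) {
    # degenerate target: the clock is the constant predictor
    return(structure(list(
      mode = obs$mode, genes = obs$genes,
      coef = stats::setNames(numeric(0), character(0)),
      intercept = stats::weighted.mean(y, weights),
      alpha = NA_real_, lambda = NA_real_, cv_mae = 0,
      provenance = list(studies = unique(obs$meta$study),
                        classes = unique(obs$meta$cell_class),
                        n_obs = nrow(x), seed = as.integer(seed),
                        schema_version = 1L)),
      class = "clock_model"))
  }
  grp <- switch(cv_groups, study = obs$meta$study, sample = obs$meta$sample_id)
  folds <- unique(grp)
  best <- list(mae = NA_real_, alpha = alphas[1], lambda = lambda)
  if (is.null(lambda)) {
    if (length(folds) < 2L) {
      stop("grouped CV by ", cv_groups, " needs at least 2 groups")
    }
    best$mae <- Inf
    for (a in alphas) {
      master <- glmnet::glmnet(x, y, weights = weights, alpha = a,
                               nlambda = nlambda)
      lams <- master$lambda
      err <- num <- numeric(length(lams))
      for (f in folds) {
        tr <- grp != f
        fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                              weights = weights[tr], alpha = a, lambda = lams)
        pred <- stats::predict(fit, x[!tr, , drop = FALSE])
        k <- ncol(pred)
        ae <- abs(pred - y[!tr]) * weights[!tr]
        err[seq_len(k)] <- err[seq_len(k)] + colSums(ae)
        if (k < length(lams)) err[(k + 1):length(lams)] <- NA
        num[seq_len(k)] <- num[seq_len(k)] + sum(weights[!tr])
      }
      mae <- err / num
      k <- which.min(mae)
      if (length(k) && mae[k] < best$mae) {
        best <- list(mae = mae[k], alpha = a, lambda = lams[k])
      }
    }
  }
  fit <- if (is.null(lambda)) {
    glmnet::glmnet(x, y, weights = weights, alpha = best$alpha,
                   nlambda = nlambda)
  } else {
    glmnet::glmnet(x, y, weights = weights, alpha = best$alpha,
                   lambda = lambda)
  }
  cf <- stats::coef(fit, s = best$lambda)
  co <- as.numeric(cf[-1, 1])
  names(co) <- obs$genes
  nz <- co[co != 0]
  structure(list(
    mode = obs$mode, genes = obs$genes, coef = nz,
    intercept = cf[1, 1], alpha = best$alpha, lambda = best$lambda,
    cv_mae = best$mae,
    provenance = list(studies = unique(obs$meta$study),
                      classes = unique(obs$meta$cell_class),
                      n_obs = nrow(x), seed = as.integer(seed),
                      schema_version = 1L)),
    class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "clock_model (%s): %d nonzero genes of %d (alpha %.2f, lambda %.4g)\n",
    x$mode, length(x$coef), length(x$genes), x$alpha, x$lambda))
  invisible(x)
}

#' Predict age from clock model
#'
#' @param object A `"clock_model"`.
#' @param newdata An `"observation_table"` (normalization mode must match the
#'   model's) or a profiles x genes matrix assumed to be in the model's mode.
#' @param allow_missing If `TRUE`, model genes absent from the profiles are
#'   imputed at 0 (with a message); more than 20% missing is still an error.
#' @param ... Unused.
#' @return Numeric vector of predicted ages (weeks).
#' @export
predict.clock_model <- function(object, newdata, allow_missing = FALSE, ...) {
  if (inherits(newdata, "observation_table")) {
    if (newdata$mode != object$mode) {
      stop("normalization mode mismatch: model is ", object$mode,
           ", profiles are ", newdata$mode)
    }
    x <- newdata$expr
  } else {
    x <- as.matrix(newdata)
  }
  genes <- names(object$coef)
  missing <- setdiff(genes, colnames(x))
  if (length(missing)) {
    if (!allow_missing) {
      stop(length(missing), " model genes missing from profiles")
    }
    if (length(missing) > 0.2 * length(genes)) {
      stop(sprintf("%d/%d model genes missing (>20%%)",
                   length(missing), length(genes)))
    }
    message(length(missing), " model genes missing; imputed at 0")
  }
  present <- intersect(genes, colnames(x))
  preds <- rep(object$intercept, nrow(x))
  if (length(present)) {
    preds <- preds +
      as.vector(x[, present, drop = FALSE] %*% object$coef[present])
  }
  preds
}

#' Per-class transcriptomic clocks
#'
#' Fits one clock per broad class on that class's rows only; classes observed
#' in fewer than 2 studies are skipped with a warning naming the class.
#'
#' @inheritParams fit_clock
#' @return Named list class -> `"clock_model"`.
#' @export
fit_celltype_clocks <- function(obs, alphas = c(0.1, 0.5, 1), nlambda = 50,
                                seed = 1L) {
  classes <- unique(obs$meta$cell_class)
  out <- list()
  for (cl in classes) {
    idx <- which(obs$meta$cell_class == cl)
    if (length(unique(obs$meta$study[idx])) < 2L) {
      warning("class ", cl, " present in fewer than 2 studies; skipped")
      next
    }
    sub <- subset_obs(obs, idx)
    out[[cl]] <- fit_clock(sub, equal_weights(sub), alphas = alphas,
                           nlambda = nlambda, seed = seed)
  }
  out
}

grouped_cv <- function(obs, group_col, alphas, nlambda, seed, weights = NULL) {
  grp <- obs$meta[[group_col]]
  folds <- unique(grp)
  if (length(folds) < 2L) {
    stop("cross-validation over ", group_col, " needs at least 2 groups")
  }
  preds <- rep(NA_real_, nrow(obs$expr))
  fold_of <- character(nrow(obs$expr))
  for (f in folds) {
    te <- which(grp == f)
    tr_obs <- subset_obs(obs, which(grp != f))
    w <- if (is.null(weights)) equal_weights(tr_obs) else weights[grp != f]
    cvg <- if (group_col == "study" &&
               length(unique(tr_obs$meta$study)) < 2L) "sample" else "study"
    model <- fit_clock(tr_obs, w, alphas = alphas, nlambda = nlambda,
                       cv_groups = cvg, seed = seed)
    preds[te] <- predict(model, subset_obs(obs, te))
    fold_of[te] <- as.character(f)
  }
  rep <- summarize_predictions(
    preds, obs$meta$age_weeks,
    groups = cbind(obs$meta[, intersect(c("study", "sample_id", "cell_class",
                                          "n_cells"), names(obs$meta)),
                            drop = FALSE],
                   fold = fold_of),
    by = "fold")
  rep$fold_col <- group_col
  rep
}

#' Leave-study-out cross-validation of the clock
#'
#' Each fold refits the clock (with equal cell-type weights recomputed on the
#' training studies, or the supplied weights subset) on all-but-one study and
#' predicts the held-out study; every observation is predicted exactly once
#' and held-out ages are never read during fitting.
#'
#' @inheritParams fit_clock
#' @return An `"eval_report"` with per-fold summaries (`per_group`).
#' @export
loso_cv <- function(obs, weights = NULL, alphas = c(0.1, 0.5, 1),
                    nlambda = 50, seed = 1L) {
  grouped_cv(obs, "study", alphas, nlambda, seed, weights)
}

#' Leave-cell-type-out cross-validation of the clock
#'
#' Each fold refits on all other classes (all studies) and predicts the
#' held-out class.
#'
#' @inheritParams fit_clock
#' @return An `"eval_report"` with per-fold summaries.
#' @export
loco_cv <- function(obs, weights = NULL, alphas = c(0.1, 0.5, 1),
                    nlambda = 50, seed = 1L) {
  grouped_cv(obs, "cell_class", alphas, nlambda, seed, weights)
}

#' Restrict an observation table to one-to-one ortholog genes
#'
#' Validates that the map is one-to-one (duplicates on either side are an
#' error listing the offenders), reduces the universe to mapped genes, and
#' renames foreign (target-namespace) profiles into the reference (source)
#' namespace so a reference-trained clock can score them.
#'
#' @param obs An `"observation_table"` whose genes are in either the source
#'   or the target namespace of the map.
#' @param map Data.frame with columns `source` and `target`.
#' @return The restricted `"observation_table"`, genes in source namespace.
#' @export
restrict_orthologs <- function(obs, map) {
  stopifnot(all(c("source", "target") %in% names(map)))
  dup_s <- unique(map$source[duplicated(map$source)])
  dup_t <- unique(map$target[duplicated(map$target)])
  if (length(dup_s) || length(dup_t)) {
    stop("ortholog map is not one-to-one; duplicated: ",
         paste(c(dup_s, dup_t), collapse = ", "))
  }
  in_source <- intersect(obs$genes, map$source)
  in_target <- intersect(obs$genes, map$target)
  if (length(in_source) == 0L && length(in_target) == 0L) {
    stop("no overlap between observation genes and the ortholog map")
  }
  if (length(in_target) > length(in_source)) {
    keep <- match(in_target, obs$genes)
    new_names <- map$source[match(in_target, map$target)]
  } else {
    keep <- match(in_source, obs$genes)
    new_names <- in_source
  }
  ord <- order(new_names)
  keep <- keep[ord]
  new_names <- new_names[ord]
  expr <- obs$expr[, keep, drop = FALSE]
  colnames(expr) <- new_names
  structure(list(expr = expr, meta = obs$meta, mode = obs$mode,
                 genes = new_names),
            class = "observation_table")
}
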