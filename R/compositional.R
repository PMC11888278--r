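comp_features <- function(comp, features) {
  x <- matrix(0, nrow(comp), length(features),
              dimnames = list(NULL, features))
  have <- intersect(features, names(comp))
  if (length(have) < length(features)) {
    warning("classes absent from composition table treated as proportion 0: ",
            paste(setdiff(features, have), collapse = ", "))
  }
  for (f in have) x[, f] <- comp[[f]]
  x
}

new_composition_model <- function(features, coefs, intercept, type,
                                  alpha = NA_real_, lambda = NA_real_,
                                  training_studies = character(0)) {
  structure(list(features = features,
                 coefficients = stats::setNames(as.numeric(coefs), features),
                 intercept = as.numeric(intercept),
                 type = type, alpha = alpha, lambda = lambda,
                 training_studies = training_studies),
            class = "composition_model")
}

#' @export
print.composition_model <- function(x, ...) {
  cat(sprintf("composition_model (%s): intercept %.3f\n", x$type, x$intercept))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Predict sample ages from a compositional model
#'
#' @param object A `"composition_model"`.
#' @param comp Composition table ([composition()] output); model classes
#'   missing from the table contribute proportion 0 with a warning.
#' @param ... Unused.
#' @return Numeric vector of predicted ages (weeks); raw regression output,
#'   not clipped to positive values.
#' @export
predict.composition_model <- function(object, comp, ...) {
  x <- comp_features(comp, object$features)
  as.vector(object$intercept + x %*% object$coefficients)
}

#' Fit a study-specific compositional age model
#'
#' Elastic-net regression of sample age on broad-class proportions, with
#' hyperparameters (alpha, lambda) selected by leave-one-sample-out
#' cross-validation minimizing MAE. Requires at least 4 distinct ages.
#'
#' @param comp Composition table for one study.
#' @param ages Numeric vector of sample ages (weeks), aligned with `comp`.
#' @param classes Feature classes; default the table's class columns.
#' @param alphas Elastic-net mixing grid.
#' @param nlambda Lambda path length per alpha.
#' @return List: `model` (a `"composition_model"`), `within_mae` (LOO MAE,
#'   weeks), `loo_pred` (LOO predictions at the selected hyperparameters).
#' @export
fit_study_model <- function(comp, ages, classes = attr(comp, "classes"),
                            alphas = seq(0.1, 1, by = 0.1), nlambda = 50) {
  if (length(unique(ages)) < 4L) {
    stop("study has fewer than 4 distinct ages (",
         length(unique(ages)), "); at least 4 time points required",
         if (!is.null(comp$study[1])) paste0(" [", comp$study[1], "]"))
  }
  if (is.null(classes)) classes <- setdiff(
    names(comp), c("study", "sample_id", "age_weeks", "n_cells"))
  x <- comp_features(comp, classes)
  n <- length(ages)
  if (all(apply(x, 2, stats::sd) == 0)) {
    # composition carries no variation: constant (training-mean) predictor
    loo <- vapply(seq_len(n), function(i) mean(ages[-i]), numeric(1))
    model <- new_composition_model(
      classes, numeric(length(classes)), mean(ages), "elasticnet",
      training_studies = unique(as.character(comp$study)))
    return(list(model = model, within_mae = mean(abs(loo - ages)),
                loo_pred = loo))
  }
  best <- list(mae = Inf)
  for (a in alphas) {
    # explicit log-spaced path: the auto path stops once deviance saturates,
    # which leaves noticeable shrinkage bias on near-noiseless studies
    lmax <- max(glmnet::glmnet(x, ages, alpha = a)$lambda)
    lams <- exp(seq(log(lmax), log(lmax * 1e-6), length.out = nlambda))
    pred <- matrix(NA_real_, n, length(lams))
    for (i in seq_len(n)) {
      fit <- glmnet::glmnet(x[-i, , drop = FALSE], ages[-i], alpha = a,
                            lambda = lams)
      pred[i, ] <- stats::predict(fit, x[i, , drop = FALSE])[1, ]
    }
    mae <- colMeans(abs(pred - ages))
    k <- which.min(mae)
    if (mae[k] < best$mae) {
      best <- list(mae = mae[k], alpha = a, lambda = lams[k],
                   loo_pred = pred[, k], path = lams)
    }
  }
  fit <- glmnet::glmnet(x, ages, alpha = best$alpha, lambda = best$path)
  cf <- stats::coef(fit, s = best$lambda)
  model <- new_composition_model(
    classes, cf[-1, 1], cf[1, 1], "elasticnet",
    alpha = best$alpha, lambda = best$lambda,
    training_studies = unique(as.character(comp$study)))
  list(model = model, within_mae = best$mae, loo_pred = best$loo_pred)
}

#' Apply a compositional model to (another) study's samples
#'
#' @param model A `"composition_model"`.
#' @param comp Composition table to predict on.
#' @param ages True ages (weeks).
#' @return An eval report ([summarize_predictions()]).
#' @export
cross_apply <- function(model, comp, ages) {
  preds <- predict(model, comp)
  summarize_predictions(preds, ages,
                        groups = data.frame(study = comp$study,
                                            sample_id = comp$sample_id))
}

#' Leave-study-out feature selection over class singles and pairs
#'
#' For every single class and unordered pair, fits an ordinary linear model of
#' age on the selected proportions over all-but-one study, measures MAE on the
#' held-out study, and averages over folds.
#'
#' @param studies List (one element per study) of lists with `comp` and `ages`.
#' @param classes Candidate classes; default the union of class columns.
#' @return Data.frame with `features` (classes joined by `+`), `n_features`,
#'   `mean_mae`; attribute `"best"` holds the argmin row's features.
#' @export
select_features <- function(studies, classes = NULL) {
  if (length(studies) < 3L) stop("feature selection needs at least 3 studies")
  if (is.null(classes)) {
    classes <- sort(unique(unlist(lapply(studies,
                                         function(s) attr(s$comp, "classes")))))
  }
  present <- vapply(classes, function(cl) {
    any(vapply(studies, function(s)
      cl %in% names(s$comp) && any(s$comp[[cl]] > 0), logical(1)))
  }, logical(1))
  if (any(!present)) {
    warning("classes absent from every study excluded: ",
            paste(classes[!present], collapse = ", "))
    classes <- classes[present]
  }
  sets <- c(lapply(classes, identity),
            utils::combn(sort(classes), 2, simplify = FALSE))
  res <- lapply(sets, function(fs) {
    maes <- vapply(seq_along(studies), function(k) {
      train <- do.call(rbind, lapply(studies[-k], function(s)
        data.frame(age = s$ages, comp_features(s$comp, fs))))
      fit <- stats::lm(age ~ ., data = train)
      test <- data.frame(comp_features(studies[[k]]$comp, fs))
      mean(abs(stats::predict(fit, test) - studies[[k]]$ages))
    }, numeric(1))
    data.frame(features = paste(fs, collapse = "+"),
               n_features = length(fs), mean_mae = mean(maes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "best") <- out$features[which.min(out$mean_mae)]
  out
}

#' Fit the meta-analytic compositional model (pooled OLS)
#'
#' Ordinary least squares of age on the selected class proportions over the
#' pooled samples of all training studies. The canonical feature pair is
#' astrocytes (expected positive coefficient) and progenitors (expected
#' negative coefficient).
#'
#' @param studies List of per-study lists with `comp` and `ages`.
#' @param features Classes to use, default `c("Astrocyte", "Progenitor")`.
#' @return A `"composition_model"` of type `"ols"`.
#' @export
fit_meta_model <- function(studies, features = c("Astrocyte", "Progenitor")) {
  pooled <- do.call(rbind, lapply(studies, function(s)
    data.frame(age = s$ages, comp_features(s$comp, features))))
  x <- cbind(1, as.matrix(pooled[, features, drop = FALSE]))
  if (qr(x)$rank < ncol(x)) stop("rank-deficient design for meta model")
  fit <- stats::lm(age ~ ., data = pooled)
  cf <- stats::coef(fit)
  new_composition_model(
    features, cf[-1], cf[1], "ols",
    training_studies = unlist(lapply(studies, function(s)
      unique(as.character(s$comp$study)))))
}
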