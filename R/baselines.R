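#' Fixed-feature baseline: random-forest selection + gradient boosting
#'
#' The conventional comparator pipeline: impurity-based random-forest
#' importance ranks the proteins of a complete (filtered + imputed)
#' training matrix, and a gradient-boosted tree classifier is fit on the
#' top `n_features`. Hyperparameters are recorded in the fit so comparisons
#' are reproducible; the fit is deterministic given `seed` (single thread).
#'
#' @param train A complete log10-state [quant_matrix()].
#' @param labels Binary class labels (second level = positive).
#' @param n_features Number of features kept (default 50, matching the
#'   relaxed set size for fair comparison).
#' @param seed Integer seed.
#' @param n_trees Random-forest trees for the ranking (default 500).
#' @param nrounds,max_depth,eta Boosting rounds (200), tree depth (3) and
#'   learning rate (0.1).
#' @return A `fixed_pipeline_fit` with a [predict()] method.
#' @export
fit_fixed_pipeline <- function(train, labels, n_features = 50, seed = 1,
                               n_trees = 500, nrounds = 200, max_depth = 3,
                               eta = 0.1) {
  stopifnot(inherits(train, "quant_matrix"))
  if (anyNA(train$values)) abort("fit_fixed_pipeline() requires a complete (imputed) matrix.")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) abort("fit_fixed_pipeline() handles binary tasks.")
  rank <- rf_importance_rank(train, labels, n_trees = n_trees, seed = seed)
  feats <- head(rank$protein_id, n_features)
  x <- train$values[, feats, drop = FALSE]
  y <- as.numeric(labels == levels(labels)[2])
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  bst <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  ))
  structure(list(
    features = feats, model = bst, classes = levels(labels),
    feature_means = colMeans(x), seed = seed,
    hyperparams = list(n_features = n_features, n_trees = n_trees,
                       nrounds = nrounds, max_depth = max_depth, eta = eta)
  ), class = "fixed_pipeline_fit")
}

#' @export
print.fixed_pipeline_fit <- function(x, ...) {
  cat(sprintf("<fixed_pipeline_fit> RF-ranked top %d features -> gradient boosting (%s vs %s)\n",
              length(x$features), x$classes[2], x$classes[1]))
  invisible(x)
}

#' @export
predict.fixed_pipeline_fit <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  x <- newdata[, object$features, drop = FALSE]
  if (anyNA(x)) abort("Missing values in `newdata`; apply a fill policy first (see non_refit_classify()).")
  predict(object$model, x)
}

#' Fixed-feature logistic baseline (no retraining)
#'
#' A single ridge logistic model trained once on a fixed feature list —
#' the non-refit sibling of the adaptive path, and its exact oracle on
#' samples that observe every feature.
#'
#' @inheritParams fit_single_sample_model
#' @return An object of class `nonrefit_logistic_fit` (an `sslr_fit` with a
#'   recorded training-mean fill point).
#' @export
fit_nonrefit_logistic <- function(train, labels, features, lambda = 1.0,
                                  min_features = 3, tol = 1e-6) {
  fit <- fit_single_sample_model(train, labels, features, lambda = lambda,
                                 min_features = min_features, tol = tol)
  fit$feature_means <- fit$center
  class(fit) <- c("nonrefit_logistic_fit", class(fit))
  fit
}

#' Score a single-sample record with a fixed (non-refit) model
#'
#' Applies a fixed-feature model to one sample without retraining. Model
#' features the sample did not quantify are handled by `fill_policy`:
#' `zero_fill` substitutes 0 (on the log10 scale), `train_mean_fill`
#' substitutes the training mean, `refuse` rejects the sample.
#'
#' @param model A `fixed_pipeline_fit` or `nonrefit_logistic_fit`.
#' @param s A [sample_record()].
#' @param fill_policy One of `"zero_fill"`, `"train_mean_fill"`, `"refuse"`.
#' @return Positive-class probability (scalar).
#' @export
non_refit_classify <- function(model, s,
                               fill_policy = c("zero_fill", "train_mean_fill", "refuse")) {
  fill_policy <- match.arg(fill_policy)
  stopifnot(inherits(s, "sample_record"))
  feats <- model$features
  x <- stats::setNames(rep(NA_real_, length(feats)), feats)
  have <- intersect(feats, names(s$quantified))
  x[have] <- s$quantified[have]
  miss <- is.na(x)
  if (any(miss)) {
    if (fill_policy == "refuse") {
      abort(paste0("Sample ", s$sample_id, " misses ", sum(miss),
                   " model features and fill_policy is \"refuse\"."),
            class = "adaptms_fill_refused")
    }
    x[miss] <- if (fill_policy == "zero_fill") 0 else model$feature_means[feats[miss]]
  }
  unname(predict(model, x))
}
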