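#' Intersect the relaxed feature set with a sample's quantified proteins
#'
#' The per-sample custom feature set: relaxed features actually measured in
#' the test sample, in relaxed-set order. An empty intersection raises a
#' condition of class `adaptms_insufficient_overlap` — a refusal to
#' classify, distinct from a low-confidence prediction.
#'
#' @param relaxed A [build_relaxed_feature_set()] result (or anything with a
#'   `protein_id` column).
#' @param s A [sample_record()].
#' @return Character vector of protein IDs in relaxed order.
#' @export
intersect_features <- function(relaxed, s) {
  stopifnot(inherits(s, "sample_record"))
  feats <- relaxed$protein_id[relaxed$protein_id %in% names(s$quantified)]
  if (length(feats) == 0) {
    abort(paste0("Insufficient overlap: sample ", s$sample_id,
                 " quantifies none of the relaxed features."),
          class = "adaptms_insufficient_overlap")
  }
  feats
}

new_adaptive_result <- function(sample_id, class_scores, features_used, coefficients,
                                classes) {
  scores <- class_scores / sum(class_scores)
  pred <- classes[which.max(scores)]  # ties -> first label in order
  structure(list(
    sample_id = sample_id,
    predicted_label = pred,
    class_scores = scores,
    features_used = features_used,
    n_features_used = length(features_used),
    coefficients = coefficients
  ), class = "adaptive_result")
}

#' @export
print.adaptive_result <- function(x, ...) {
  cat(sprintf("<adaptive_result> %s -> %s (%.3f), %d features used\n",
              x$sample_id, x$predicted_label, max(x$class_scores), x$n_features_used))
  invisible(x)
}

#' @describeIn classify_sample one row per class score.
#' @param x An `adaptive_result`.
#' @param ... Ignored.
#' @exportS3Method generics::tidy
tidy.adaptive_result <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    class = names(x$class_scores),
    score = unname(x$class_scores),
    predicted = names(x$class_scores) == x$predicted_label
  )
}

#' @describeIn classify_sample one-row summary (prediction, top score,
#'   feature count).
#' @exportS3Method generics::glance
glance.adaptive_result <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    predicted_label = x$predicted_label,
    top_score = max(x$class_scores),
    n_features_used = x$n_features_used
  )
}

fit_cached <- function(cache, key, fit_fun) {
  if (is.null(cache)) return(fit_fun())
  if (!exists(key, envir = cache, inherits = FALSE)) {
    assign(key, fit_fun(), envir = cache)
  }
  get(key, envir = cache, inherits = FALSE)
}

#' Classify one sample by de novo model retraining
#'
#' The core adaptive step: the relaxed feature set is intersected with the
#' proteins the test sample actually quantified, a ridge logistic model is
#' retrained on the discovery data restricted to that intersection, and the
#' sample is scored using its own (never imputed) log10 values standardized
#' by training statistics. The result is a deterministic pure function of
#' (train, labels, relaxed, s): repeated calls return bit-identical scores,
#' and no confidence interval is defined for a single classification.
#'
#' @param train Complete log10-state [quant_matrix()] used for refitting
#'   (see [prepare_refit_matrix()]); values on the relaxed features must be
#'   non-missing.
#' @param labels Binary class labels for `train`'s samples.
#' @param relaxed A [build_relaxed_feature_set()] result.
#' @param s A [sample_record()].
#' @param lambda,min_features,tol See [fit_single_sample_model()].
#' @param cache Optional environment; refits are keyed by the intersected
#'   feature tuple. Caching never changes any output.
#' @return An `adaptive_result`: predicted label, class scores summing to 1,
#'   features used, and fitted coefficients for transparency.
#' @export
classify_sample <- function(train, labels, relaxed, s, lambda = 1.0,
                            min_features = 3, tol = 1e-6, cache = NULL) {
  feats <- intersect_features(relaxed, s)
  fit <- fit_cached(cache, paste(feats, collapse = "\r"), function() {
    fit_single_sample_model(train, labels, feats, lambda = lambda,
                            min_features = min_features, tol = tol)
  })
  p_pos <- predict(fit, s$quantified[fit$features])
  new_adaptive_result(
    sample_id = s$sample_id,
    class_scores = stats::setNames(c(1 - p_pos, p_pos), fit$classes),
    features_used = fit$features,
    coefficients = stats::setNames(tidy(fit)$estimate, tidy(fit)$term),
    classes = fit$classes
  )
}

#' Classify one sample with one-vs-rest multiclass retraining
#'
#' For k >= 3 classes: one binary ridge logistic model per class (that class
#' vs the rest) is retrained on the intersected features; the per-class
#' positive scores are renormalized to sum to 1 and the argmax (ties broken
#' by label order) is the prediction. With k = 2 this degenerates to the
#' binary path (up to solver floating point).
#'
#' @inheritParams classify_sample
#' @param labels Class labels; every class must be present in training.
#' @return An `adaptive_result` with one score per class.
#' @export
classify_sample_multiclass <- function(train, labels, relaxed, s, lambda = 1.0,
                                       min_features = 3, tol = 1e-6, cache = NULL) {
  labels <- droplevels(as.factor(labels))
  lev <- levels(labels)
  if (length(lev) < 2) abort("At least two classes required.")
  feats <- intersect_features(relaxed, s)
  raw <- purrr::map_dbl(lev, function(cl) {
    y <- factor(ifelse(labels == cl, cl, "rest"), levels = c("rest", cl))
    fit <- fit_cached(cache, paste(c(cl, feats), collapse = "\r"), function() {
      fit_single_sample_model(train, y, feats, lambda = lambda,
                              min_features = min_features, tol = tol)
    })
    predict(fit, s$quantified[fit$features])
  })
  new_adaptive_result(
    sample_id = s$sample_id,
    class_scores = stats::setNames(raw, lev),
    features_used = feats,
    coefficients = NULL,
    classes = lev
  )
}

#' Classify a batch of samples independently
#'
#' Element-wise application of [classify_sample()] (or the one-vs-rest
#' multiclass path when `labels` has three or more levels). Each sample's
#' result depends only on its own record; per-sample failures (e.g. zero
#' relaxed-feature overlap) are recorded in the `status` column and the
#' batch continues.
#'
#' @inheritParams classify_sample
#' @param samples List of [sample_record()]s.
#' @return A tibble with one row per sample: `sample_id`, `status` (`"ok"`
#'   or the refusal reason), `predicted_label`, `score` (positive-class
#'   probability, binary only), `n_features_used`, and list-columns
#'   `class_scores` and `result` (the full `adaptive_result`).
#' @export
classify_batch <- function(train, labels, relaxed, samples, lambda = 1.0,
                           min_features = 3, tol = 1e-6) {
  labels_f <- droplevels(as.factor(labels))
  binary <- nlevels(labels_f) == 2
  cache <- new.env(parent = emptyenv())
  rows <- purrr::map(samples, function(s) {
    res <- tryCatch(
      {
        r <- if (binary) {
          classify_sample(train, labels_f, relaxed, s, lambda = lambda,
                          min_features = min_features, tol = tol, cache = cache)
        } else {
          classify_sample_multiclass(train, labels_f, relaxed, s, lambda = lambda,
                                     min_features = min_features, tol = tol,
                                     cache = cache)
        }
        list(status = "ok", result = r)
      },
      adaptms_insufficient_overlap = function(e) list(status = "insufficient_overlap", result = NULL),
      adaptms_insufficient_features = function(e) list(status = "insufficient_features", result = NULL),
      error = function(e) list(status = paste0("error: ", conditionMessage(e)), result = NULL)
    )
    r <- res$result
    tibble::tibble(
      sample_id = s$sample_id,
      status = res$status,
      predicted_label = if (is.null(r)) NA_character_ else r$predicted_label,
      score = if (!is.null(r) && binary) unname(r$class_scores[2]) else NA_real_,
      n_features_used = if (is.null(r)) NA_integer_ else r$n_features_used,
      class_scores = list(if (is.null(r)) NULL else r$class_scores),
      result = list(r)
    )
  })
  dplyr::bind_rows(rows)
}

#' One-time completion of the refit training matrix
#'
#' Restricts the discovery matrix to the relaxed features and applies a
#' single KNN imputation so that every per-sample refit sees complete
#' training values. Relaxed features were testable during selection, so
#' they carry enough observations for neighbour imputation; proteins outside
#' the relaxed set never enter a refit and are not imputed. Test samples are
#' never imputed.
#'
#' A training sample observing none of the relaxed features carries no
#' neighbour information on this restriction; its row is filled with the
#' per-protein observed means (with a warning) before KNN imputation.
#'
#' @param m Log10-state discovery [quant_matrix()].
#' @param relaxed A [build_relaxed_feature_set()] result.
#' @param k KNN neighbour count (default 5).
#' @return A complete `quant_matrix` over the relaxed features.
#' @export
prepare_refit_matrix <- function(m, relaxed, k = 5) {
  stopifnot(inherits(m, "quant_matrix"))
  feats <- intersect(relaxed$protein_id, colnames(m$values))
  if (length(feats) == 0) abort("No relaxed feature present in the training matrix.")
  sub <- m[, feats]
  empty <- rowSums(!is.na(sub$values)) == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " training sample(s) observe no relaxed feature; ",
                "filled with per-protein means for refitting."))
    means <- colMeans(sub$values, na.rm = TRUE)
    sub$values[empty, ] <- rep(means, each = sum(empty))
  }
  knn_impute(sub, k = k)
}

#' Serialize adaptive results
#'
#' Writes a list of `adaptive_result`s (or a [classify_batch()] tibble) as a
#' JSON array (sample_id, predicted_label, class_scores, features_used,
#' coefficients) and, optionally, a flat TSV summary.
#'
#' @param results List of `adaptive_result`s or a `classify_batch()` tibble.
#' @param path JSON output path.
#' @param tsv_path Optional TSV summary path.
#' @return `path`, invisibly.
#' @export
write_adaptive_results <- function(results, path, tsv_path = NULL) {
  if (is.data.frame(results)) {
    tbl <- results
    objs <- results$result
  } else {
    objs <- results
    tbl <- dplyr::bind_rows(purrr::map(objs, glance))
  }
  payload <- purrr::map(objs, function(r) {
    if (is.null(r)) return(list(status = "failed"))
    list(
      sample_id = r$sample_id,
      predicted_label = r$predicted_label,
      class_scores = as.list(r$class_scores),
      features_used = r$features_used,
      coefficients = if (is.null(r$coefficients)) NULL else as.list(r$coefficients)
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(tsv_path)) {
    flat <- tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE]
    readr::write_tsv(flat, tsv_path)
  }
  invisible(path)
}
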