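#' Derive independent sub-seeds from one top-level seed
#' @noRd
make_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' ROC curve and AUC
#'
#' AUC as the Mann-Whitney pairwise-concordance statistic (ties counted
#' one half), computed via ranks; the ROC curve by a sweep over the unique
#' score thresholds, starting at (0, 0) and ending at (1, 1).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truth Binary truth: logical, 0/1, or a factor whose second level
#'   is the positive class.
#' @return A `roc_result`: list with `auc` and `roc_points` (tibble
#'   `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, truth) {
  if (is.factor(truth)) truth <- truth == levels(truth)[2]
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) abort("`scores` and `truth` lengths differ.")
  ok <- !is.na(scores) & !is.na(truth)
  scores <- scores[ok]; truth <- truth[ok]
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) abort("Both classes must be present to compute ROC/AUC.")
  r <- rank(scores)  # midranks: ties counted 1/2
  auc <- (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(truth[ord]); fp <- cumsum(!truth[ord])
  # one ROC point per distinct threshold (last index of each tied block)
  keep <- which(!duplicated(scores[ord], fromLast = TRUE))
  pts <- tibble::tibble(
    fpr = c(0, fp[keep] / n_neg),
    tpr = c(0, tp[keep] / n_pos)
  )
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- dplyr::bind_rows(pts, tibble::tibble(fpr = 1, tpr = 1))
  }
  structure(list(auc = auc, roc_points = pts), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n", x$auc, nrow(x$roc_points)))
  invisible(x)
}

#' Pipeline configuration for the evaluation harness
#'
#' Bundles the tunable parameters every evaluation mode shares. Defaults
#' follow the package-wide conventions: 10 subsampling rounds of 80%,
#' alpha = 0.05, 50 requested features, KNN k = 5, ridge strength 1,
#' minimum 3 usable features, 5% completeness filter for the complete-matrix
#' baseline path, zero fill for non-refit scoring.
#'
#' @param n_rounds,subsample_frac,alpha,n_requested,fallback See
#'   [build_relaxed_feature_set()]; `fallback` defaults to `"rank"` here so
#'   null cohorts still produce (noise) feature sets.
#' @param k KNN neighbours.
#' @param lambda,min_features Classifier controls.
#' @param max_missing_frac Completeness filter for the fixed baseline path.
#' @param fill_policy Fill policy for non-refit scoring.
#' @return A named list of class `adapt_config`.
#' @export
adapt_config <- function(n_rounds = 10, subsample_frac = 0.8, alpha = 0.05,
                         n_requested = 50, fallback = "rank", k = 5,
                         lambda = 1.0, min_features = 3,
                         max_missing_frac = 0.05, fill_policy = "zero_fill") {
  structure(list(
    n_rounds = n_rounds, subsample_frac = subsample_frac, alpha = alpha,
    n_requested = n_requested, fallback = fallback, k = k, lambda = lambda,
    min_features = min_features, max_missing_frac = max_missing_frac,
    fill_policy = fill_policy
  ), class = "adapt_config")
}

#' Fit one of the three classification strategies on a training matrix
#'
#' Shared fitting entry point of the evaluation harness. `"adaptive"` builds
#' the relaxed set and the one-time-completed refit matrix for per-sample
#' retraining; `"nonrefit_logistic"` trains a single ridge logistic model on
#' the full relaxed set, applied without retraining under the config's fill
#' policy; `"fixed_xgb"` is the conventional complete-matrix pipeline
#' (5% completeness filter, KNN imputation, RF feature ranking, gradient
#' boosting).
#'
#' @param method `"adaptive"`, `"nonrefit_logistic"`, or `"fixed_xgb"`.
#' @param train Log10-state [quant_matrix()] (may contain missing values).
#' @param labels Binary class labels.
#' @param config An [adapt_config()].
#' @param seed Seed for subsampling / tree fitting.
#' @return An `adapt_pipeline_fit`; score samples with
#'   [predict_samples()].
#' @export
fit_pipeline <- function(method = c("adaptive", "nonrefit_logistic", "fixed_xgb"),
                         train, labels, config = adapt_config(), seed = 1) {
  method <- match.arg(method)
  labels <- droplevels(as.factor(labels))
  obj <- list(method = method, labels = labels, config = config, seed = seed)
  if (method %in% c("adaptive", "nonrefit_logistic")) {
    relaxed <- build_relaxed_feature_set(
      train, labels, n_rounds = config$n_rounds,
      subsample_frac = config$subsample_frac, alpha = config$alpha,
      n_requested = config$n_requested, seed = seed, fallback = config$fallback
    )
    refit <- prepare_refit_matrix(train, relaxed, k = config$k)
    obj$relaxed <- relaxed
    obj$refit <- refit
    if (method == "nonrefit_logistic") {
      obj$model <- fit_nonrefit_logistic(
        refit, labels, colnames(refit$values),
        lambda = config$lambda, min_features = config$min_features
      )
    }
  } else {
    prep <- prepare_training(train, max_missing_frac = config$max_missing_frac,
                             k = config$k)
    obj$model <- fit_fixed_pipeline(prep, labels, n_features = config$n_requested,
                                    seed = seed)
  }
  structure(obj, class = "adapt_pipeline_fit")
}

#' Score a list of sample records with a fitted pipeline
#'
#' @param fit An [fit_pipeline()] result.
#' @param samples List of [sample_record()]s.
#' @return Tibble `sample_id`, `status`, `score` (positive-class
#'   probability), `n_features_used` (adaptive only).
#' @export
predict_samples <- function(fit, samples) {
  stopifnot(inherits(fit, "adapt_pipeline_fit"))
  if (fit$method == "adaptive") {
    out <- classify_batch(fit$refit, fit$labels, fit$relaxed, samples,
                          lambda = fit$config$lambda,
                          min_features = fit$config$min_features)
    return(out[, c("sample_id", "status", "score", "n_features_used", "predicted_label")])
  }
  rows <- purrr::map(samples, function(s) {
    sc <- tryCatch(
      list(status = "ok",
           score = non_refit_classify(fit$model, s, fill_policy = fit$config$fill_policy)),
      adaptms_fill_refused = function(e) list(status = "fill_refused", score = NA_real_),
      error = function(e) list(status = paste0("error: ", conditionMessage(e)),
                               score = NA_real_)
    )
    lev <- levels(fit$labels)
    tibble::tibble(
      sample_id = s$sample_id, status = sc$status, score = sc$score,
      n_features_used = NA_integer_,
      predicted_label = if (is.na(sc$score)) NA_character_ else
        if (sc$score > 0.5) lev[2] else lev[1]
    )
  })
  dplyr::bind_rows(rows)
}

new_evaluation_report <- function(per_sample, auc_per_repeat, method, extra = list()) {
  pooled <- roc_auc(per_sample$score, per_sample$truth)
  rep <- c(list(
    per_sample = per_sample,
    auc_per_repeat = auc_per_repeat,
    auc = mean(auc_per_repeat),
    auc_ci = if (length(auc_per_repeat) > 1) {
      unname(quantile(auc_per_repeat, c(0.025, 0.975)))
    } else c(NA_real_, NA_real_),
    roc_points = pooled$roc_points,
    method = method
  ), extra)
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  ci <- if (all(is.na(x$auc_ci))) "" else sprintf(" [%.3f, %.3f]", x$auc_ci[1], x$auc_ci[2])
  cat(sprintf("<evaluation_report> %s: mean AUC %.3f%s over %d repeat(s)\n",
              x$method, x$auc, ci, length(x$auc_per_repeat)))
  invisible(x)
}

#' @describeIn repeated_cv one-row summary of an evaluation report.
#' @param x An `evaluation_report`.
#' @param ... Ignored.
#' @exportS3Method generics::glance
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    method = x$method, auc = x$auc,
    ci_low = x$auc_ci[1], ci_high = x$auc_ci[2],
    n_repeats = length(x$auc_per_repeat),
    n_scored = sum(!is.na(x$per_sample$score))
  )
}

#' Stratified fold assignment
#' @noRd
make_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (ix in split(seq_along(labels), labels)) {
    folds[sample(ix)] <- rep_len(seq_len(n_folds), length(ix))
  }
  folds
}

#' Repeated stratified cross-validation
#'
#' Stratified k-fold cross-validation of a full pipeline, repeated with
#' fresh fold assignments. Within every training fold the whole pipeline —
#' feature selection (and, where the method needs it, imputation) included —
#' is refit from scratch, so no information leaks into the held-out fold;
#' held-out samples are scored from their raw records (observed values
#' only). The AUC confidence interval is the 2.5/97.5 percentile over
#' repeats.
#'
#' @param m Log10-state [quant_matrix()].
#' @param labels Binary class labels (each class >= `n_folds` samples).
#' @param n_folds Folds (default 5, stratified).
#' @param n_repeats Repeats (default 10).
#' @param seed Top-level seed; all fold randomness derives from it.
#' @param method,config See [fit_pipeline()].
#' @return An `evaluation_report`.
#' @export
repeated_cv <- function(m, labels, n_folds = 5, n_repeats = 10, seed = 1,
                        method = "adaptive", config = adapt_config()) {
  labels <- droplevels(as.factor(labels))
  if (any(table(labels) < n_folds)) {
    abort("Every class needs at least `n_folds` samples for stratified CV.")
  }
  seeds <- make_seeds(seed, n_repeats)
  per_repeat <- purrr::map(seq_len(n_repeats), function(r) {
    folds <- withr::with_seed(seeds[r], make_folds(labels, n_folds))
    rows <- purrr::map(seq_len(n_folds), function(f) {
      tr <- folds != f
      fit <- fit_pipeline(method, m[tr, ], labels[tr], config = config,
                          seed = seeds[r] %% 1000000L + f)
      test_ids <- rownames(m$values)[!tr]
      records <- purrr::map(test_ids, ~ as_sample_record(m, .x))
      scored <- predict_samples(fit, records)
      scored$truth <- labels[!tr]
      scored$fold <- f
      scored
    })
    out <- dplyr::bind_rows(rows)
    out$rep <- r
    out
  })
  per_sample <- dplyr::bind_rows(per_repeat)
  auc_per_repeat <- purrr::map_dbl(per_repeat, ~ roc_auc(.x$score, .x$truth)$auc)
  new_evaluation_report(per_sample, auc_per_repeat, method,
                        extra = list(n_folds = n_folds, seed = seed))
}

#' Learning curve: validation AUC vs training-set size
#'
#' For each requested size, repeated stratified subsampling of the training
#' cohort, a full pipeline refit, and evaluation on a fixed validation set.
#'
#' @param train,train_labels Training matrix and labels.
#' @param valid,valid_labels Validation matrix and labels (scored as raw
#'   per-sample records).
#' @param sizes Training-set sizes to evaluate; sizes that cannot hold at
#'   least two samples of every class are skipped with a warning.
#' @param n_repeats Subsampling repeats per size (default 10).
#' @param seed Top-level seed.
#' @param method,config See [fit_pipeline()].
#' @return A `learning_curve` tibble: `n_train`, `mean_auc`, `ci_low`,
#'   `ci_high`; per-repeat AUCs in attribute `"per_repeat"`.
#' @export
learning_curve <- function(train, train_labels, valid, valid_labels,
                           sizes = c(50, 100, 200), n_repeats = 10, seed = 1,
                           method = "adaptive", config = adapt_config()) {
  train_labels <- droplevels(as.factor(train_labels))
  valid_labels <- droplevels(as.factor(valid_labels))
  records <- purrr::map(rownames(valid$values), ~ as_sample_record(valid, .x))
  props <- table(train_labels) / length(train_labels)
  seeds <- make_seeds(seed, length(sizes) * n_repeats)
  per_repeat <- list()
  rows <- list()
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    n_cl <- round(props * size)
    if (any(n_cl < 2) || size > length(train_labels)) {
      warn(paste0("Skipping size ", size, ": infeasible class allocation."))
      next
    }
    aucs <- purrr::map_dbl(seq_len(n_repeats), function(r) {
      sd <- seeds[(si - 1) * n_repeats + r]
      sub <- withr::with_seed(sd, {
        sort(unlist(purrr::map(names(n_cl), function(cl) {
          ix <- which(train_labels == cl)
          sample(ix, min(n_cl[[cl]], length(ix)))
        }), use.names = FALSE))
      })
      fit <- fit_pipeline(method, train[sub, ], train_labels[sub],
                          config = config, seed = sd)
      scored <- predict_samples(fit, records)
      roc_auc(scored$score, valid_labels)$auc
    })
    per_repeat[[as.character(size)]] <- aucs
    rows[[length(rows) + 1]] <- tibble::tibble(
      n_train = size, mean_auc = mean(aucs),
      ci_low = unname(quantile(aucs, 0.025)),
      ci_high = unname(quantile(aucs, 0.975))
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "per_repeat") <- per_repeat
  class(out) <- c("learning_curve", class(out))
  out
}

#' Per-sample feature-usage diagnostics
#'
#' Summarizes how many features each classified sample actually used,
#' split by classification correctness (argmax prediction vs truth) —
#' the diagnostic showing that correctly and incorrectly classified samples
#' draw from similar feature-count distributions. Summary statistics are
#' boxplot conventions: median, quartiles, and whiskers at 1.5 x IQR.
#'
#' @param results A [classify_batch()] tibble (or anything with
#'   `sample_id`, `predicted_label`, `n_features_used`).
#' @param truth True labels, named by sample ID or aligned with `results`.
#' @return A `feature_usage` list: `per_sample` tibble and `summary` tibble
#'   (one row per correctness group; groups with no samples are flagged in
#'   attribute `"empty_groups"`).
#' @export
feature_usage_summary <- function(results, truth) {
  if (!is.null(names(truth))) truth <- truth[results$sample_id]
  per_sample <- tibble::tibble(
    sample_id = results$sample_id,
    n_features_used = results$n_features_used,
    correct = as.character(results$predicted_label) == as.character(truth)
  )
  per_sample <- per_sample[!is.na(per_sample$n_features_used), ]
  summarize_grp <- function(x) {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75)))
    iqr <- q[3] - q[1]
    tibble::tibble(
      n = length(x), median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
      whisker_high = max(x[x <= q[3] + 1.5 * iqr])
    )
  }
  groups <- split(per_sample$n_features_used, per_sample$correct)
  summary <- dplyr::bind_rows(purrr::imap(groups, function(x, nm) {
    tibble::add_column(summarize_grp(x), correct = as.logical(nm), .before = 1)
  }))
  empty <- setdiff(c("TRUE", "FALSE"), names(groups))
  out <- structure(list(per_sample = per_sample, summary = summary),
                   class = "feature_usage")
  attr(out, "empty_groups") <- as.logical(empty)
  out
}

#' @export
print.feature_usage <- function(x, ...) {
  cat("<feature_usage>\n")
  print(x$summary)
  invisible(x)
}

#' Cross-site evaluation
#'
#' Trains the pipeline on the samples of `train_sites` only and adaptively
#' classifies every sample of each test site, emulating
#' external-cohort validation. Training and test site sets must be
#' disjoint. Pooled multi-site training is expressed by passing several
#' sites in `train_sites`.
#'
#' @param m Log10-state [quant_matrix()] spanning all sites.
#' @param metadata Metadata with `sample_id`, the label column and a site
#'   column.
#' @param train_sites,test_sites Disjoint character vectors of site names.
#' @param label_column,site_column Metadata column names.
#' @param method,config,seed See [fit_pipeline()].
#' @return Tibble: one row per test site with `site`, `auc`, `n_scored`,
#'   `n_flagged`; per-sample scores in attribute `"per_sample"`.
#' @export
cross_site_eval <- function(m, metadata, train_sites, test_sites,
                            label_column = "class", site_column = "site",
                            method = "adaptive", config = adapt_config(),
                            seed = 1) {
  if (length(intersect(train_sites, test_sites)) > 0) {
    abort("Training and test site sets must be disjoint.")
  }
  md <- metadata[match(rownames(m$values), metadata$sample_id), ]
  site <- as.character(md[[site_column]])
  labels <- droplevels(as.factor(md[[label_column]]))
  tr <- site %in% train_sites
  if (!any(tr)) abort("No samples in the training sites.")
  fit <- fit_pipeline(method, m[tr, ], labels[tr], config = config, seed = seed)
  rows <- purrr::map(test_sites, function(ts) {
    te <- which(site == ts)
    if (length(te) == 0) abort(paste0("No samples at site ", ts))
    records <- purrr::map(rownames(m$values)[te], ~ as_sample_record(m, .x))
    scored <- predict_samples(fit, records)
    scored$truth <- labels[te]
    scored$site <- ts
    scored
  })
  per_sample <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(purrr::map(rows, function(sc) {
    ok <- !is.na(sc$score)
    tibble::tibble(
      site = sc$site[1],
      auc = roc_auc(sc$score[ok], sc$truth[ok])$auc,
      n_scored = sum(ok),
      n_flagged = sum(!ok)
    )
  }))
  attr(out, "per_sample") <- per_sample
  class(out) <- c("cross_site_eval", class(out))
  out
}
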