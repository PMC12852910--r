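#' Covariate constraints for cohort matching
#'
#' Building blocks of a [cohort_query()]: `constraint_exact()` keeps samples
#' whose categorical covariate equals the query patient's value (or lies in
#' an explicit `values` set); `constraint_window()` keeps samples whose
#' continuous covariate lies within `tolerance` of the query patient's
#' value (closed interval, boundary values included).
#'
#' @param values Optional explicit set of admissible values; default `NULL`
#'   means "equal to the query patient's value".
#' @param tolerance Half-width of the window around the query value (same
#'   units as the covariate, e.g. years for age).
#' @return A constraint object.
#' @export
constraint_exact <- function(values = NULL) {
  structure(list(type = "exact", values = values), class = "cohort_constraint")
}

#' @rdname constraint_exact
#' @export
constraint_window <- function(tolerance) {
  if (!is.numeric(tolerance) || tolerance < 0) abort("`tolerance` must be non-negative.")
  structure(list(type = "window", tolerance = tolerance), class = "cohort_constraint")
}

#' Declare a retrospective cohort-matching task
#'
#' Describes how to slice a proteome database into a task-specific training
#' cohort for a query patient: the metadata column defining the diagnostic
#' label, an optional recoding of its values, hard per-covariate constraints
#' relative to the query patient, and optional class balancing.
#'
#' @param label_column Metadata column holding the class label.
#' @param label_map Optional named character vector recoding label values
#'   (`c(old = "new", ...)`); labels not named are kept as is.
#' @param constraints Named list of [constraint_exact()] /
#'   [constraint_window()] objects, names = metadata columns.
#' @param balancing `"none"` or `"downsample_to_min_class"` (random
#'   downsampling of majority classes with `seed`).
#' @param min_per_class Minimum class size after matching (default 2;
#'   must be >= 2).
#' @param seed Seed for balancing.
#' @return A `cohort_query` object.
#' @export
cohort_query <- function(label_column, label_map = NULL, constraints = list(),
                         balancing = c("none", "downsample_to_min_class"),
                         min_per_class = 2, seed = 1) {
  balancing <- match.arg(balancing)
  if (min_per_class < 2) abort("`min_per_class` must be at least 2.")
  if (length(constraints) > 0) {
    if (is.null(names(constraints)) || any(names(constraints) == "")) {
      abort("`constraints` must be a named list (names = metadata columns).")
    }
    ok <- vapply(constraints, inherits, logical(1), "cohort_constraint")
    if (!all(ok)) abort("Every constraint must be constraint_exact() or constraint_window().")
  }
  structure(list(
    label_column = label_column, label_map = label_map,
    constraints = constraints, balancing = balancing,
    min_per_class = min_per_class, seed = seed
  ), class = "cohort_query")
}

#' Assemble a matched training cohort from a proteome database
#'
#' Retrospective cohort slicing: returns exactly the database samples that
#' satisfy every constraint relative to the query patient's covariates,
#' with labels taken from the query's label column (after recoding) and
#' optional downsampling to the minority class size. The query patient is
#' always excluded from its own training cohort. The matching report
#' (attribute `"report"`, JSON-serializable) lists per-constraint exclusion
#' counts.
#'
#' @param db A log10-state [quant_matrix()] database.
#' @param metadata Metadata tibble with `sample_id` plus label and covariate
#'   columns, one row per database sample.
#' @param query_covariates Named list (or one-row data frame) of the query
#'   patient's covariate values.
#' @param q A [cohort_query()].
#' @param query_sample_id Optional ID to exclude from the database.
#' @return A list with `matrix` (the `quant_matrix` slice), `labels`
#'   (factor) and `report`; class `matched_cohort`.
#' @export
match_cohort <- function(db, metadata, query_covariates, q, query_sample_id = NULL) {
  stopifnot(inherits(db, "quant_matrix"), inherits(q, "cohort_query"))
  metadata <- tibble::as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) abort("Metadata must contain `sample_id`.")
  if (!q$label_column %in% names(metadata)) {
    abort(paste0("Label column `", q$label_column, "` not found in metadata."))
  }
  if (!setequal(metadata$sample_id, rownames(db$values))) {
    abort("Database matrix and metadata must share the same sample IDs.")
  }
  query_covariates <- as.list(query_covariates)
  md <- metadata[match(rownames(db$values), metadata$sample_id), ]

  keep <- rep(TRUE, nrow(md))
  report <- list(n_database = nrow(md), exclusions = list())
  if (!is.null(query_sample_id)) {
    hit <- md$sample_id == query_sample_id
    report$exclusions[["query_patient"]] <- sum(keep & hit)
    keep <- keep & !hit
  }
  for (cov in names(q$constraints)) {
    con <- q$constraints[[cov]]
    if (!cov %in% names(md)) abort(paste0("Constrained covariate `", cov, "` not in metadata."))
    if (con$type == "exact") {
      admissible <- con$values %||% query_covariates[[cov]]
      if (is.null(admissible)) abort(paste0("Query patient lacks covariate `", cov, "`."))
      pass <- md[[cov]] %in% admissible
    } else {
      qv <- query_covariates[[cov]]
      if (is.null(qv) || !is.numeric(qv)) {
        abort(paste0("Query patient needs a numeric value for covariate `", cov, "`."))
      }
      if (!is.numeric(md[[cov]])) abort(paste0("Covariate `", cov, "` is not numeric in metadata."))
      pass <- !is.na(md[[cov]]) & abs(md[[cov]] - qv) <= con$tolerance
    }
    report$exclusions[[cov]] <- sum(keep & !pass)
    keep <- keep & pass
  }

  labels <- as.character(md[[q$label_column]])
  if (!is.null(q$label_map)) {
    mapped <- q$label_map[labels]
    labels <- ifelse(is.na(mapped), labels, mapped)
  }
  idx <- which(keep)
  tab <- table(labels[idx])
  low <- tab < q$min_per_class
  if (length(tab) == 0 || any(low)) {
    limiting <- if (length(report$exclusions) > 0) {
      names(report$exclusions)[which.max(unlist(report$exclusions))]
    } else "no constraint"
    abort(sprintf(
      "Matched cohort below min_per_class = %d for class(es) %s (most exclusions from constraint `%s`).",
      q$min_per_class,
      if (length(tab) == 0) "(all)" else paste(names(tab)[low], collapse = ", "),
      limiting
    ))
  }
  if (q$balancing == "downsample_to_min_class") {
    n_min <- min(tab)
    idx <- withr::with_seed(q$seed, {
      sort(unlist(purrr::map(split(idx, labels[idx]), function(ix) {
        if (length(ix) > n_min) sample(ix, n_min) else ix
      }), use.names = FALSE))
    })
  }
  report$n_matched <- length(idx)
  report$class_sizes <- as.list(table(labels[idx]))
  structure(list(
    matrix = db[idx, ],
    labels = factor(labels[idx]),
    report = report
  ), class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d samples (%s)\n", nrow(x$matrix$values),
              paste(sprintf("%s: %d", names(x$report$class_sizes),
                            unlist(x$report$class_sizes)), collapse = ", ")))
  invisible(x)
}

#' Answer one diagnostic question for one patient sample
#'
#' End-to-end retrospective task: a matched training cohort is assembled
#' from the database via [match_cohort()], the relaxed feature set is built
#' on it, the refit matrix is completed once, and the query sample is
#' classified adaptively (binary or one-vs-rest depending on the matched
#' label set). Multiple distinct queries can be run against the same
#' [sample_record()] without re-measurement.
#'
#' @inheritParams match_cohort
#' @param s The query patient's [sample_record()].
#' @param n_rounds,subsample_frac,alpha,n_requested,fallback Passed to
#'   [build_relaxed_feature_set()].
#' @param k Imputation neighbours for the refit matrix.
#' @param lambda,min_features Passed to the classifier.
#' @param seed Seed for the feature-selection subsampling.
#' @return An `adaptive_result` with the matching report in attribute
#'   `"matching_report"`.
#' @export
run_task <- function(db, metadata, s, query_covariates, q,
                     n_rounds = 10, subsample_frac = 0.8, alpha = 0.05,
                     n_requested = 50, fallback = "error", k = 5,
                     lambda = 1.0, min_features = 3, seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }
  cohort <- stage("match_cohort",
                  match_cohort(db, metadata, query_covariates, q,
                               query_sample_id = s$sample_id))
  relaxed <- stage("feature_selection",
                   build_relaxed_feature_set(cohort$matrix, cohort$labels,
                                             n_rounds = n_rounds,
                                             subsample_frac = subsample_frac,
                                             alpha = alpha, n_requested = n_requested,
                                             seed = seed, fallback = fallback))
  refit <- stage("preprocessing", prepare_refit_matrix(cohort$matrix, relaxed, k = k))
  res <- stage("classification", {
    if (nlevels(cohort$labels) == 2) {
      classify_sample(refit, cohort$labels, relaxed, s,
                      lambda = lambda, min_features = min_features)
    } else {
      classify_sample_multiclass(refit, cohort$labels, relaxed, s,
                                 lambda = lambda, min_features = min_features)
    }
  })
  attr(res, "matching_report") <- cohort$report
  res
}
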