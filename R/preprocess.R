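#' Remove proteins exceeding a missingness threshold
#'
#' Cohort-level completeness filter: proteins missing in more than
#' `max_missing_frac` of samples are removed (strictly greater; a protein
#' missing in exactly the threshold fraction is retained). The sample set is
#' unchanged. The removed protein IDs are attached as attribute
#' `"removed_proteins"` and available via [removed_proteins()].
#'
#' @param m A [quant_matrix()].
#' @param max_missing_frac Maximum tolerated missing fraction per protein
#'   (default 0.05, i.e. proteins missing in more than 5% of samples are
#'   dropped).
#' @return The filtered `quant_matrix` with attribute `removed_proteins`.
#' @export
filter_completeness <- function(m, max_missing_frac = 0.05) {
  stopifnot(inherits(m, "quant_matrix"))
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    abort("`max_missing_frac` must be in [0, 1].")
  }
  v <- m$values
  if (nrow(v) < 1) abort("Matrix must contain at least one sample.")
  n_missing <- colSums(is.na(v))
  # strict "> threshold" removal; +1e-9 guards k/n vs binary-fraction rounding
  keep <- n_missing <= max_missing_frac * nrow(v) + 1e-9
  if (!any(keep)) {
    abort(sprintf(
      "All %d proteins exceed the completeness threshold (max missing fraction %.3g).",
      ncol(v), max_missing_frac
    ))
  }
  out <- quant_matrix(v[, keep, drop = FALSE], transform = m$transform)
  attr(out, "removed_proteins") <- colnames(v)[!keep]
  out
}

#' @rdname filter_completeness
#' @export
removed_proteins <- function(m) attr(m, "removed_proteins") %||% character()

#' Pairwise-complete Euclidean distances between samples
#'
#' Distance over mutually observed proteins, rescaled by the proportion of
#' coordinates used so that sparsity does not shrink distances:
#' d(i, j) = sqrt(P / m_ij * sum over mutual proteins (x - y)^2), with P the
#' total protein count and m_ij the mutual observation count. Pairs with no
#' mutual coordinate get distance Inf.
#' @noRd
sample_distances <- function(v) {
  obs <- !is.na(v)
  x <- v
  x[!obs] <- 0
  x2 <- x^2
  obs_n <- obs * 1
  cross <- tcrossprod(x)
  s2 <- tcrossprod(x2, obs_n)
  counts <- tcrossprod(obs_n)
  d2 <- s2 + t(s2) - 2 * cross
  d2[d2 < 0] <- 0  # numerical noise
  d <- sqrt(ncol(v) / counts * d2)
  d[counts == 0] <- Inf
  diag(d) <- 0
  d
}

#' K-nearest-neighbour imputation of a log10 matrix
#'
#' Replaces each missing entry by the unweighted mean of that protein's
#' observed values among the k nearest samples, with Euclidean sample-sample
#' distance computed over mutually observed proteins and rescaled by the
#' proportion of coordinates used. Neighbours are ranked by distance (ties
#' broken by sample order) and the ranking is walked until k samples with
#' the protein observed are found; if fewer than k exist, all of them are
#' used. Observed entries are never altered; the output is complete.
#'
#' This path exists for the fixed-feature baselines and the one-time
#' training-matrix completion — test samples are never imputed.
#'
#' @param m A log10-state [quant_matrix()]; every sample must have at least
#'   one observed value.
#' @param k Neighbour count (default 5).
#' @return A complete `quant_matrix`.
#' @export
knn_impute <- function(m, k = 5) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$transform != "log10") abort("knn_impute() expects a log10-state matrix.")
  if (k < 1) abort("`k` must be at least 1.")
  v <- m$values
  if (!anyNA(v)) return(m)
  obs <- !is.na(v)
  never <- colSums(obs) == 0
  if (any(never)) {
    abort(paste0(
      "Proteins observed in no sample (filter them first): ",
      paste(colnames(v)[never], collapse = ", ")
    ))
  }
  if (any(rowSums(obs) == 0)) abort("Every sample must have at least one observed value.")
  d <- sample_distances(v)
  n <- nrow(v)
  out <- v
  for (i in seq_len(n)) {
    miss_j <- which(!obs[i, ])
    if (length(miss_j) == 0) next
    # stable neighbour ranking: distance, then sample index
    nb <- setdiff(order(d[i, ], seq_len(n)), i)
    for (j in miss_j) {
      donors <- nb[obs[nb, j]]
      use <- donors[seq_len(min(k, length(donors)))]
      out[i, j] <- mean(v[use, j])
    }
  }
  quant_matrix(out, transform = m$transform)
}

#' Filter, impute and return a complete training matrix
#'
#' Convenience composition of the complete-matrix preprocessing used by the
#' fixed-feature baselines: optional log10 transform, completeness filter,
#' then one-time KNN imputation.
#'
#' @param m A [quant_matrix()] (raw or log10).
#' @param max_missing_frac Completeness threshold, see
#'   [filter_completeness()].
#' @param k KNN neighbour count, see [knn_impute()].
#' @return A complete log10-state `quant_matrix`.
#' @export
prepare_training <- function(m, max_missing_frac = 0.05, k = 5) {
  if (m$transform == "raw") m <- log10_transform(m)
  knn_impute(filter_completeness(m, max_missing_frac), k = k)
}
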