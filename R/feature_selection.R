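#' Vectorized Welch statistics for all proteins, two groups.
#' Returns tibble(protein_id, n1, n2, t, p_value, testable); pairwise-complete
#' per protein. Proteins with <2 observed values in either group are marked
#' untestable. A zero standard error with zero mean difference yields t = 0,
#' p = 1.
#' @noRd
welch_stats <- function(v, g1, g2) {
  stats_grp <- function(rows) {
    x <- v[rows, , drop = FALSE]
    obs <- !is.na(x)
    n <- colSums(obs)
    x0 <- x
    x0[!obs] <- 0
    s <- colSums(x0)
    mean <- ifelse(n > 0, s / n, NA_real_)
    ctr <- sweep(x0, 2, ifelse(is.na(mean), 0, mean))
    ctr[!obs] <- 0
    ss <- colSums(ctr^2)
    vr <- ifelse(n > 1, ss / (n - 1), NA_real_)
    list(n = n, mean = mean, var = vr)
  }
  a <- stats_grp(g1)
  b <- stats_grp(g2)
  testable <- a$n >= 2 & b$n >= 2
  se2 <- a$var / a$n + b$var / b$n
  diff <- a$mean - b$mean
  t <- ifelse(testable & se2 > 0, diff / sqrt(se2),
              ifelse(testable & abs(diff) < .Machine$double.eps^0.5, 0, NA_real_))
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  p <- ifelse(is.na(t), NA_real_,
              ifelse(t == 0 & se2 <= 0, 1, 2 * pt(-abs(t), df)))
  # degenerate: both groups constant but unequal -> infinite t, p = 0
  p[testable & se2 <= 0 & abs(diff) >= .Machine$double.eps^0.5] <- 0
  t[testable & se2 <= 0 & abs(diff) >= .Machine$double.eps^0.5] <-
    sign(diff[testable & se2 <= 0 & abs(diff) >= .Machine$double.eps^0.5]) * Inf
  tibble::tibble(
    protein_id = colnames(v), n1 = unname(a$n), n2 = unname(b$n),
    t = unname(t), p_value = unname(p),
    testable = unname(testable & !is.na(t))
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector; monotone and
#' clipped to at most 1. Thin validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  stats::p.adjust(p, method = "BH")
}

#' Rank proteins by Welch t-test between two classes
#'
#' Per protein, a Welch (unequal-variance) two-sample t statistic on the
#' observed values only (pairwise-complete), with Benjamini-Hochberg FDR
#' adjustment across proteins. Returns the proteins significant at `alpha`,
#' ranked by absolute t statistic. Proteins with fewer than two observed
#' values in either class are excluded from testing and reported in the
#' `"skipped"` attribute; the full per-protein table is in attribute
#' `"all_stats"`.
#'
#' @param m A log10-state [quant_matrix()].
#' @param labels Binary class labels (factor or coercible), one per sample.
#' @param alpha FDR level (default 0.05).
#' @return Tibble with `protein_id`, `t`, `p_value`, `p_adjusted`, sorted by
#'   `abs(t)` descending.
#' @export
welch_t_rank <- function(m, labels, alpha = 0.05) {
  stopifnot(inherits(m, "quant_matrix"))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) abort("welch_t_rank() needs exactly two classes.")
  if (length(labels) != nrow(m$values)) abort("One label per sample required.")
  if (any(table(labels) < 2)) abort("Both classes need at least two samples.")
  st <- welch_stats(m$values,
                    which(labels == levels(labels)[1]),
                    which(labels == levels(labels)[2]))
  tested <- st[st$testable, ]
  tested$p_adjusted <- bh_adjust(tested$p_value)
  sel <- tested[tested$p_adjusted <= alpha, c("protein_id", "t", "p_value", "p_adjusted")]
  sel <- sel[order(-abs(sel$t), sel$protein_id), ]
  out <- tibble::as_tibble(sel)
  attr(out, "skipped") <- st$protein_id[!st$testable]
  attr(out, "all_stats") <- tibble::as_tibble(
    tested[order(-abs(tested$t), tested$protein_id),
           c("protein_id", "t", "p_value", "p_adjusted")]
  )
  out
}

#' Rank proteins by pairwise Welch t-tests across k classes
#'
#' Multiclass univariate selection: for every unordered class pair a Welch
#' t-test per protein, with BH adjustment across proteins within each pair.
#' A protein qualifies if any pair reaches `alpha`; ranking is by the
#' maximum absolute t over pairs.
#'
#' @param m A log10-state [quant_matrix()].
#' @param labels Class labels with at least three levels.
#' @param alpha FDR level per pair (default 0.05).
#' @return Tibble with `protein_id`, `max_abs_t`, `min_p_adjusted`, sorted
#'   by `max_abs_t` descending; attributes as [welch_t_rank()].
#' @export
pairwise_t_rank <- function(m, labels, alpha = 0.05) {
  stopifnot(inherits(m, "quant_matrix"))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 3) abort("pairwise_t_rank() needs at least three classes.")
  if (any(table(labels) < 2)) abort("Every class needs at least two samples.")
  lev <- levels(labels)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  per_pair <- purrr::map(pairs, function(pr) {
    st <- welch_stats(m$values, which(labels == pr[1]), which(labels == pr[2]))
    st$p_adjusted <- NA_real_
    st$p_adjusted[st$testable] <- bh_adjust(st$p_value[st$testable])
    st
  })
  abs_t <- do.call(cbind, purrr::map(per_pair, ~ abs(.x$t)))
  padj <- do.call(cbind, purrr::map(per_pair, ~ .x$p_adjusted))
  any_tested <- rowSums(!is.na(abs_t)) > 0
  all_tbl <- tibble::tibble(
    protein_id = colnames(m$values),
    max_abs_t = apply(abs_t, 1, function(z) if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)),
    min_p_adjusted = apply(padj, 1, function(z) if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE))
  )[any_tested, ]
  all_tbl <- all_tbl[order(-all_tbl$max_abs_t, all_tbl$protein_id), ]
  out <- all_tbl[all_tbl$min_p_adjusted <= alpha, ]
  attr(out, "skipped") <- setdiff(colnames(m$values), all_tbl$protein_id)
  attr(out, "all_stats") <- all_tbl
  attr(out, "n_pairs") <- length(pairs)
  out
}

#' Random-forest importance ranking
#'
#' Impurity-based (Gini) variable importance from a random forest fit on a
#' complete matrix, for the fixed-feature baseline path. Deterministic given
#' `seed` (single-threaded).
#'
#' @param m A complete [quant_matrix()] (filter + impute applied).
#' @param labels Class labels.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return Tibble `protein_id`, `importance`, sorted descending.
#' @export
rf_importance_rank <- function(m, labels, n_trees = 500, seed = 1) {
  stopifnot(inherits(m, "quant_matrix"))
  if (anyNA(m$values)) abort("rf_importance_rank() requires a complete (imputed) matrix.")
  labels <- droplevels(as.factor(labels))
  x <- m$values
  colnames(x) <- make.names(colnames(x))  # ranger needs syntactic names
  fit <- ranger::ranger(
    x = x, y = labels, num.trees = n_trees, importance = "impurity",
    seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance
  ord <- order(-imp, colnames(x))
  tibble::tibble(protein_id = colnames(m$values)[ord], importance = unname(imp[ord]))
}

new_relaxed_feature_set <- function(df, params) {
  tibble::new_tibble(df, params = params,
                     class = c("relaxed_feature_set", "tbl_df", "tbl", "data.frame"))
}

#' Parameters of a relaxed feature set
#' @param x A [build_relaxed_feature_set()] result.
#' @return Named list of the selection parameters.
#' @export
relaxed_params <- function(x) attr(x, "params")

#' Build a relaxed feature set by repeated subsampled selection
#'
#' The candidate list that per-sample retraining draws from. For each of
#' `n_rounds` rounds, a class-stratified random subset of the samples
#' (fraction `subsample_frac`, without replacement) is drawn and univariate
#' selection is run on it: Welch t-tests for two classes, pairwise t-tests
#' for three or more, BH-adjusted at `alpha`. Per-round selections are
#' aggregated into a per-protein selection frequency and a mean absolute t
#' statistic over the rounds in which the protein was testable; the top
#' `n_requested` features under the ordering (frequency desc, mean |t| desc,
#' protein ID asc) form the set. Deliberately broader than any single
#' selection run, this reduces dependence on cohort composition.
#'
#' @param m A log10-state [quant_matrix()].
#' @param labels Class labels (2 for binary, >= 3 for multiclass).
#' @param n_rounds Number of subsampling rounds (default 10).
#' @param subsample_frac Fraction of each class drawn per round (default
#'   0.8; in (0, 1]).
#' @param alpha FDR level per round (default 0.05).
#' @param n_requested Maximum feature count (default 50, where validation
#'   performance typically plateaus).
#' @param seed Integer seed; the whole construction is reproducible from it.
#' @param fallback What to do when a round selects nothing at `alpha`:
#'   `"error"`, or `"rank"` to take that round's top `n_requested` proteins
#'   by absolute t regardless of significance.
#' @return A `relaxed_feature_set`: a tibble `protein_id`,
#'   `selection_frequency`, `mean_abs_stat` with the parameters in attribute
#'   `params` (see [relaxed_params()]).
#' @export
build_relaxed_feature_set <- function(m, labels, n_rounds = 10, subsample_frac = 0.8,
                                      alpha = 0.05, n_requested = 50, seed = 1,
                                      fallback = c("error", "rank")) {
  stopifnot(inherits(m, "quant_matrix"))
  fallback <- match.arg(fallback)
  if (n_rounds < 1) abort("`n_rounds` must be at least 1.")
  if (subsample_frac <= 0 || subsample_frac > 1) abort("`subsample_frac` must be in (0, 1].")
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(m$values)) abort("One label per sample required.")
  task <- if (nlevels(labels) == 2) "binary" else "multiclass"
  rank_fun <- if (task == "binary") welch_t_rank else pairwise_t_rank
  stat_col <- if (task == "binary") "t" else "max_abs_t"

  idx_by_class <- split(seq_along(labels), labels)
  if (any(lengths(idx_by_class) < 2)) abort("Every class needs at least two samples.")

  rounds <- withr::with_seed(seed, {
    purrr::map(seq_len(n_rounds), function(r) {
      sub <- sort(unlist(purrr::map(idx_by_class, function(ix) {
        n_draw <- max(2, round(subsample_frac * length(ix)))
        n_draw <- min(n_draw, length(ix))
        sample(ix, n_draw)
      }), use.names = FALSE))
      sel <- rank_fun(m[sub, ], labels[sub], alpha = alpha)
      all_stats <- attr(sel, "all_stats")
      selected <- sel$protein_id
      if (length(selected) == 0) {
        if (fallback == "rank" && nrow(all_stats) > 0) {
          selected <- head(all_stats$protein_id, n_requested)
        }
      }
      list(selected = selected,
           abs_stat = stats::setNames(abs(all_stats[[stat_col]]), all_stats$protein_id))
    })
  })

  if (all(lengths(purrr::map(rounds, "selected")) == 0)) {
    abort(paste0(
      "No feature was selected in any of ", n_rounds, " rounds at alpha = ", alpha,
      ". Consider raising `alpha` or using fallback = \"rank\" to take the top ",
      n_requested, " features by |t|."
    ))
  }

  sel_counts <- table(unlist(purrr::map(rounds, "selected"), use.names = FALSE))
  stat_long <- unlist(purrr::map(rounds, "abs_stat"))
  stat_names <- unlist(purrr::map(rounds, ~ names(.x$abs_stat)))
  mean_stat <- tapply(stat_long, stat_names, mean)

  ids <- names(sel_counts)
  df <- tibble::tibble(
    protein_id = ids,
    selection_frequency = as.numeric(sel_counts[ids]) / n_rounds,
    mean_abs_stat = as.numeric(mean_stat[ids])
  )
  df <- df[order(-df$selection_frequency, -df$mean_abs_stat, df$protein_id), ]
  df <- head(df, n_requested)
  out <- new_relaxed_feature_set(df, params = list(
    n_rounds = n_rounds, subsample_frac = subsample_frac, alpha = alpha,
    n_requested = n_requested, seed = seed, task = task, fallback = fallback
  ))
  attr(out, "round_counts") <- lengths(purrr::map(rounds, "selected"))
  out
}

#' @export
print.relaxed_feature_set <- function(x, ...) {
  p <- relaxed_params(x)
  cat(sprintf("<relaxed_feature_set> %d features (%s task; %d rounds x %.0f%% subsamples, alpha = %g)\n",
              nrow(x), p$task, p$n_rounds, 100 * p$subsample_frac, p$alpha))
  NextMethod()
}

#' Serialize / read a relaxed feature set
#'
#' The set is written as a TSV (`protein_id`, `selection_frequency`,
#' `mean_abs_stat`) with the selection parameters in a JSON sidecar at
#' `<path>.params.json`.
#'
#' @param x A `relaxed_feature_set`.
#' @param path TSV path.
#' @return `path` invisibly; `read_relaxed_set()` returns the set.
#' @export
write_relaxed_set <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  jsonlite::write_json(relaxed_params(x), paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_relaxed_set
#' @export
read_relaxed_set <- function(path) {
  df <- readr::read_tsv(path, col_types = "cdd", progress = FALSE)
  side <- paste0(path, ".params.json")
  params <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  new_relaxed_feature_set(df, params = params)
}
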