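# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results with naive loops, separate from
# the package's vectorized implementations.

# Exhaustive pairwise-concordance AUC: count concordant positive-negative
# pairs, ties as 1/2.
oracle_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Brute-force KNN imputation: for every missing entry, enumerate all pairwise
# coverage-rescaled Euclidean distances, walk the (distance, index) ranking
# and average the first k donors that observe the protein.
oracle_knn_impute <- function(v, k = 5) {
  n <- nrow(v); p <- ncol(v)
  out <- v
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (u in seq_len(n)) {
      if (u == i) next
      mutual <- which(!is.na(v[i, ]) & !is.na(v[u, ]))
      if (length(mutual) == 0) next
      d[u] <- sqrt(p / length(mutual) * sum((v[i, mutual] - v[u, mutual])^2))
    }
    ranking <- setdiff(order(d, seq_len(n)), i)
    for (j in seq_len(p)) {
      if (!is.na(v[i, j])) next
      donors <- ranking[!is.na(v[ranking, j])]
      use <- donors[seq_len(min(k, length(donors)))]
      out[i, j] <- mean(v[use, j])
    }
  }
  out
}

# Welch statistic evaluated directly from the defining formula.
oracle_welch_t <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

# Random log10-scale quant matrix with controlled missingness.
random_qm <- function(n, p, miss_frac = 0, seed = 1, prefix = "P") {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n * p, mean = 3, sd = 1), n, p,
                dimnames = list(sprintf("s%02d", seq_len(n)),
                                sprintf("%s%03d", prefix, seq_len(p))))
    if (miss_frac > 0) {
      drop <- matrix(runif(n * p) < miss_frac, n, p)
      # keep at least one observation per sample and per protein
      for (j in which(colSums(!drop) == 0)) drop[sample(n, 1), j] <- FALSE
      for (i in which(rowSums(!drop) == 0)) drop[i, sample(p, 1)] <- FALSE
      v[drop] <- NA_real_
    }
    quant_matrix(v, transform = "log10")
  })
}

# A small two-class cohort with a clean planted signal, for classifier tests.
toy_cohort <- function(n_per_class = 30, n_proteins = 60, n_informative = 8,
                       effect = 2, seed = 1) {
  generate_cohort(synthetic_config(
    n_per_class = c(a = n_per_class, b = n_per_class),
    n_proteins = n_proteins, n_informative = n_informative,
    effect_size = effect, seed = seed
  ))
}

records_of <- function(m) {
  lapply(rownames(m$values), function(id) as_sample_record(m, id))
}
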