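test_that("BH adjustment matches the step-up recursion and clips at 1", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Welch t matches the defining formula and stats::t.test", {
  a <- c(0.9, 1.0, 1.1); b <- c(1.9, 2.0, 2.1)
  v <- rbind(matrix(a, 3, 1), matrix(b, 3, 1))
  dimnames(v) <- list(sprintf("s%d", 1:6), "P1")
  qm <- quant_matrix(cbind(v, P2 = rnorm(6, 3)), transform = "log10")
  colnames(qm$values) <- c("P1", "P2")
  res <- welch_t_rank(qm, rep(c("A", "B"), each = 3), alpha = 1)
  t_hand <- oracle_welch_t(a, b)
  expect_equal(res$t[res$protein_id == "P1"], t_hand, tolerance = 1e-12)

  # random matrices against t.test, protein by protein
  for (seed in 1:5) {
    qm <- random_qm(14, 10, miss_frac = 0.15, seed = 100 + seed)
    labels <- rep(c("A", "B"), 7)
    res <- welch_t_rank(qm, labels, alpha = 1)
    all_stats <- attr(res, "all_stats")
    for (pid in all_stats$protein_id) {
      x <- qm$values[labels == "A", pid]; y <- qm$values[labels == "B", pid]
      tt <- t.test(x[!is.na(x)], y[!is.na(y)])
      row <- all_stats[all_stats$protein_id == pid, ]
      expect_equal(row$t, unname(tt$statistic), tolerance = 1e-9)
      expect_equal(row$p_value, tt$p.value, tolerance = 1e-9)
    }
  }
})

test_that("a protein with no class difference is not selected; sparse ones are skipped", {
  withr::with_seed(7, {
    v <- cbind(null = rnorm(20, 3, 0.5), sparse = c(3, rep(NA, 19)),
               real = c(rnorm(10, 2), rnorm(10, 4)))
    rownames(v) <- sprintf("s%02d", 1:20)
  })
  qm <- quant_matrix(v, transform = "log10")
  res <- welch_t_rank(qm, rep(c("A", "B"), each = 10), alpha = 0.05)
  expect_false("null" %in% res$protein_id)
  expect_true("real" %in% res$protein_id)
  expect_identical(attr(res, "skipped"), "sparse")
})

test_that("under a global null the selected fraction stays near the FDR level", {
  fracs <- vapply(1:5, function(seed) {
    qm <- random_qm(40, 1000, seed = 200 + seed)
    nrow(welch_t_rank(qm, rep(c("A", "B"), 20), alpha = 0.05)) / 1000
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("pairwise selection tests all class pairs and finds one-class shifts", {
  withr::with_seed(11, {
    n <- 45
    v <- cbind(marker3 = c(rnorm(30, 3, 0.3), rnorm(15, 4.5, 0.3)),
               noise = rnorm(n, 3, 0.3))
    rownames(v) <- sprintf("s%02d", 1:n)
  })
  qm <- quant_matrix(v, transform = "log10")
  labels <- rep(c("c1", "c2", "c3"), each = 15)
  res <- pairwise_t_rank(qm, labels, alpha = 0.05)
  expect_equal(attr(res, "n_pairs"), 3L)  # C(3, 2)
  expect_true("marker3" %in% res$protein_id)
  expect_false("noise" %in% res$protein_id)
})

test_that("planted multiclass markers rank above null proteins", {
  hits <- vapply(1:5, function(seed) {
    co <- generate_cohort(synthetic_config(
      n_per_class = c(30, 30, 30), n_proteins = 100, n_informative = 2,
      effect_size = 2, mnar_a = -10, seed = 300 + seed
    ))
    res <- pairwise_t_rank(co$matrix, co$metadata$class, alpha = 1)
    all(co$ground_truth$informative %in%
          head(res$protein_id, length(co$ground_truth$informative)))
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("random-forest importance ranks a separating protein first, reproducibly", {
  withr::with_seed(21, {
    v <- cbind(sep = c(rnorm(25, 1, 0.1), rnorm(25, 5, 0.1)),
               matrix(rnorm(50 * 9, 3), 50, 9))
    colnames(v) <- c("sep", sprintf("n%d", 1:9))
    rownames(v) <- sprintf("s%02d", 1:50)
  })
  qm <- quant_matrix(v, transform = "log10")
  labels <- rep(c("A", "B"), each = 25)
  r1 <- rf_importance_rank(qm, labels, n_trees = 200, seed = 5)
  r2 <- rf_importance_rank(qm, labels, n_trees = 200, seed = 5)
  expect_equal(r1$protein_id[1], "sep")
  expect_identical(r1, r2)
  expect_error(rf_importance_rank(random_qm(6, 4, miss_frac = 0.3, seed = 1), rep(c("A", "B"), 3)),
               "complete")
})

test_that("with permuted labels the separating protein loses its top rank", {
  withr::with_seed(22, {
    v <- cbind(sep = c(rnorm(25, 1, 0.1), rnorm(25, 5, 0.1)),
               matrix(rnorm(50 * 19, 3), 50, 19))
    colnames(v) <- c("sep", sprintf("n%d", 1:19))
    rownames(v) <- sprintf("s%02d", 1:50)
    qm <- quant_matrix(v, transform = "log10")
    top_hits <- vapply(1:5, function(i) {
      perm <- sample(rep(c("A", "B"), each = 25))
      rf_importance_rank(qm, perm, n_trees = 200, seed = i)$protein_id[1] == "sep"
    }, logical(1))
  })
  expect_lte(sum(top_hits), 2)
})

test_that("one near-full round reduces the relaxed set to a truncated t-ranking", {
  co <- toy_cohort(seed = 13)
  labels <- co$metadata$class
  rel <- build_relaxed_feature_set(co$matrix, labels, n_rounds = 1,
                                   subsample_frac = 1, alpha = 0.05,
                                   n_requested = 5, seed = 1)
  direct <- welch_t_rank(co$matrix, labels, alpha = 0.05)
  expect_identical(rel$protein_id, head(direct$protein_id, 5))
  expect_true(all(rel$selection_frequency == 1))
})

test_that("relaxed set construction is reproducible and orders by frequency first", {
  co <- toy_cohort(seed = 14)
  a <- build_relaxed_feature_set(co$matrix, co$metadata$class, seed = 42)
  b <- build_relaxed_feature_set(co$matrix, co$metadata$class, seed = 42)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_true(all(diff(a$selection_frequency) <= 0))
  expect_true(all(a$selection_frequency >= 0 & a$selection_frequency <= 1))
  expect_lte(nrow(a), relaxed_params(a)$n_requested)
  # ever-present features precede all others
  full <- a$selection_frequency == 1
  if (any(full) && any(!full)) {
    expect_lt(max(which(full)), min(which(!full)))
  }
})

test_that("selection failure suggests the fallback, and the fallback works", {
  null_qm <- random_qm(20, 50, seed = 31)
  labels <- rep(c("A", "B"), 10)
  expect_error(
    build_relaxed_feature_set(null_qm, labels, alpha = 1e-6, seed = 1),
    "alpha"
  )
  rel <- build_relaxed_feature_set(null_qm, labels, alpha = 1e-6, seed = 1,
                                   n_requested = 10, fallback = "rank")
  expect_equal(nrow(rel), 10)
})

test_that("relaxed sets round-trip through the TSV + sidecar serialization", {
  co <- toy_cohort(seed = 15)
  rel <- build_relaxed_feature_set(co$matrix, co$metadata$class, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_relaxed_set(rel, path)
  back <- read_relaxed_set(path)
  expect_equal(as.data.frame(back), as.data.frame(rel), ignore_attr = TRUE)
  expect_equal(relaxed_params(back)$n_rounds, relaxed_params(rel)$n_rounds)
})
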