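test_that("AUC hand cases: perfect separation, interleaved, complete ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "Both classes")
})

test_that("AUC equals the exhaustive pairwise-concordance oracle", {
  withr::with_seed(101, {
    for (i in 1:50) {
      n <- sample(4:12, 1)
      truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)  # rounding forces ties
      expect_equal(roc_auc(scores, truth)$auc, oracle_auc(scores, truth),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(103, {
    for (i in 1:5) {
      truth <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
      scores <- rnorm(40) + truth
      ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
      expect_equal(roc_auc(scores, truth)$auc, ref, tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(107, {
    truth <- sample(0:1, 30, replace = TRUE)
    truth[1:2] <- c(0, 1)
    scores <- rnorm(30)
  })
  base <- roc_auc(scores, truth)$auc
  expect_equal(roc_auc(exp(scores), truth)$auc, base)
  expect_equal(roc_auc(2 * scores + 7, truth)$auc, base)
  expect_equal(roc_auc(stats::plogis(scores), truth)$auc, base)
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
  withr::with_seed(109, {
    truth <- sample(0:1, 25, replace = TRUE); truth[1:2] <- c(0, 1)
    scores <- round(rnorm(25), 1)
  })
  pts <- roc_auc(scores, truth)$roc_points
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("repeated CV with one repeat and a fixed seed is deterministic end to end", {
  co <- toy_cohort(n_per_class = 25, n_proteins = 80, seed = 111)
  r1 <- repeated_cv(co$matrix, co$metadata$class, n_repeats = 1, seed = 13)
  r2 <- repeated_cv(co$matrix, co$metadata$class, n_repeats = 1, seed = 13)
  expect_identical(r1$per_sample$score, r2$per_sample$score)
  expect_identical(r1$auc, r2$auc)
  expect_error(repeated_cv(co$matrix, rep(c("A", "B"), c(4, 46)), n_folds = 5),
               "n_folds")
})

test_that("strong planted signal yields high CV AUC with a percentile CI", {
  co <- generate_cohort(synthetic_config(
    n_per_class = c(50, 50), n_proteins = 300, n_informative = 15,
    effect_size = 2, seed = 113
  ))
  rep <- repeated_cv(co$matrix, co$metadata$class, n_repeats = 3, seed = 7)
  expect_gt(rep$auc, 0.9)
  expect_length(rep$auc_per_repeat, 3)
  expect_lte(rep$auc_ci[1], rep$auc_ci[2])
  g <- glance(rep)
  expect_equal(g$n_repeats, 3)
})

test_that("selecting features outside the folds inflates null AUC", {
  qm <- random_qm(40, 150, seed = 127)
  labels <- factor(rep(c("A", "B"), 20))
  inside <- repeated_cv(qm, labels, n_repeats = 2, seed = 3,
                        config = adapt_config(n_requested = 10))
  # leaky variant: rank features once on ALL samples, then CV only the classifier
  leaky_feats <- head(attr(welch_t_rank(qm, labels, alpha = 1), "all_stats")$protein_id, 10)
  folds <- withr::with_seed(5, {
    f <- integer(40)
    for (ix in split(1:40, labels)) f[sample(ix)] <- rep_len(1:5, length(ix))
    f
  })
  leaky_scores <- numeric(40)
  for (f in 1:5) {
    tr <- folds != f
    imp <- knn_impute(qm[tr, leaky_feats])
    fit <- fit_nonrefit_logistic(imp, labels[tr], leaky_feats)
    for (i in which(!tr)) {
      s <- as_sample_record(qm, rownames(qm$values)[i])
      leaky_scores[i] <- non_refit_classify(fit, s, "train_mean_fill")
    }
  }
  leaky_auc <- roc_auc(leaky_scores, labels)$auc
  expect_gt(leaky_auc, inside$auc + 0.1)
  expect_lt(inside$auc, 0.65)
})

test_that("feature-usage summaries reproduce hand-computed boxplot statistics", {
  results <- tibble::tibble(
    sample_id = paste0("s", 1:5),
    predicted_label = c("A", "A", "B", "B", "A"),
    n_features_used = c(10L, 14L, 12L, 30L, 11L)
  )
  truth <- c(s1 = "A", s2 = "B", s3 = "B", s4 = "B", s5 = "B")
  fu <- feature_usage_summary(results, truth)
  # correct: s1 (10), s3 (12), s4 (30); incorrect: s2 (14), s5 (11)
  corr <- fu$summary[fu$summary$correct == TRUE, ]
  expect_equal(corr$median, 12)
  expect_equal(corr$q1, unname(quantile(c(10, 12, 30), 0.25)))
  expect_equal(corr$q3, unname(quantile(c(10, 12, 30), 0.75)))
  inc <- fu$summary[fu$summary$correct == FALSE, ]
  expect_equal(inc$median, 12.5)
  expect_equal(inc$n, 2)
})

test_that("an all-correct batch flags the empty incorrect group", {
  results <- tibble::tibble(sample_id = c("a", "b"),
                            predicted_label = c("x", "y"),
                            n_features_used = c(5L, 6L))
  fu <- feature_usage_summary(results, c(a = "x", b = "y"))
  expect_identical(attr(fu, "empty_groups"), FALSE)
  expect_equal(nrow(fu$summary), 1)
})

test_that("learning curves are seed-stable and saturate at the full training set", {
  co <- generate_cohort(synthetic_config(
    n_per_class = c(40, 40), n_proteins = 120, n_informative = 10,
    effect_size = 2, seed = 131
  ))
  val <- generate_cohort(synthetic_config(
    n_per_class = c(25, 25), n_proteins = 120, n_informative = 10,
    effect_size = 2, seed = 132
  ))
  lc1 <- learning_curve(co$matrix, co$metadata$class, val$matrix,
                        val$metadata$class, sizes = c(30, 80), n_repeats = 3,
                        seed = 17, config = adapt_config(n_requested = 15))
  lc2 <- learning_curve(co$matrix, co$metadata$class, val$matrix,
                        val$metadata$class, sizes = c(30, 80), n_repeats = 3,
                        seed = 17, config = adapt_config(n_requested = 15))
  expect_identical(lc1$mean_auc, lc2$mean_auc)
  # at size = full training set only selection subsampling varies across
  # repeats, so the repeat spread is narrow and brackets a direct fit
  full_aucs <- attr(lc1, "per_repeat")[["80"]]
  expect_lt(max(full_aucs) - min(full_aucs), 0.1)
  fit <- fit_pipeline("adaptive", co$matrix, co$metadata$class,
                      config = adapt_config(n_requested = 15), seed = 17)
  expect_true(abs(mean(full_aucs) -
                    roc_auc(predict_samples(fit, records_of(val$matrix))$score,
                            factor(val$metadata$class))$auc) < 0.05)
  # infeasible sizes are skipped with a warning
  expect_warning(
    learning_curve(co$matrix, co$metadata$class, val$matrix, val$metadata$class,
                   sizes = c(2, 30), n_repeats = 1, seed = 3,
                   config = adapt_config(n_requested = 10)),
    "Skipping"
  )
})

test_that("cross-site evaluation requires disjoint site sets and scores per site", {
  co <- generate_multisite(synthetic_config(
    n_per_class = c(20, 20), n_proteins = 120, n_informative = 10,
    effect_size = 2, n_sites = 2, site_effect_sd = 0.1, seed = 137
  ))
  expect_error(
    cross_site_eval(co$matrix, co$metadata, "site1", "site1"),
    "disjoint"
  )
  res <- cross_site_eval(co$matrix, co$metadata, "site1", "site2",
                         config = adapt_config(n_requested = 15), seed = 3)
  expect_equal(res$site, "site2")
  expect_gt(res$auc, 0.8)
  expect_equal(res$n_scored + res$n_flagged, 40)
})

test_that("autoplot methods return ggplot objects", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_s3_class(autoplot(r), "ggplot")
  co <- toy_cohort(n_per_class = 20, n_proteins = 50, seed = 139)
  expect_s3_class(autoplot(missingness_profile(co$matrix)), "ggplot")
})
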