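make_relaxed <- function(ids) {
  # minimal hand-built relaxed set for intersection tests
  structure(
    tibble::tibble(protein_id = ids,
                   selection_frequency = 1,
                   mean_abs_stat = rev(seq_along(ids))),
    class = c("relaxed_feature_set", class(tibble::tibble())),
    params = list(task = "binary")
  )
}

test_that("feature intersection preserves relaxed order and refuses disjoint sets", {
  rel <- make_relaxed(paste0("P", 1:5))
  s <- sample_record(c(P9 = 1, P4 = 2, P2 = 3), "t")
  expect_identical(intersect_features(rel, s), c("P2", "P4"))
  s_all <- sample_record(stats::setNames(1:5, paste0("P", 1:5)), "t2")
  expect_identical(intersect_features(rel, s_all), paste0("P", 1:5))
  s_none <- sample_record(c(Q1 = 1), "t3")
  expect_error(intersect_features(rel, s_none),
               class = "adaptms_insufficient_overlap")
})

test_that("ridge refit: sign follows the class direction, penalty shrinks monotonically", {
  withr::with_seed(5, {
    v <- cbind(up = c(rnorm(20, 2, 0.3), rnorm(20, 3, 0.3)),
               n1 = rnorm(40, 3, 0.3), n2 = rnorm(40, 3, 0.3))
    rownames(v) <- sprintf("s%02d", 1:40)
  })
  qm <- quant_matrix(v, transform = "log10")
  labels <- rep(c("ctrl", "case"), each = 20)  # case = second level? factor order
  labels <- factor(labels, levels = c("ctrl", "case"))
  fit <- fit_single_sample_model(qm, labels, c("up", "n1", "n2"))
  # "case" has the larger mean on `up`, so its coefficient is positive
  expect_gt(tidy(fit)$estimate[tidy(fit)$term == "up"], 0)

  norm2 <- function(lam) {
    f <- fit_single_sample_model(qm, labels, c("up", "n1", "n2"), lambda = lam)
    sum(f$w^2)
  }
  expect_gt(norm2(1), norm2(2))
  expect_gt(norm2(2), norm2(4))
})

test_that("the vanishing-penalty limit agrees with glm()", {
  withr::with_seed(6, {
    v <- cbind(a = rnorm(60, 3, 0.5), b = rnorm(60, 3, 0.5), c = rnorm(60, 3, 0.5))
    rownames(v) <- sprintf("s%02d", 1:60)
    y <- rbinom(60, 1, stats::plogis(1.2 * scale(v[, "a"])))
  })
  qm <- quant_matrix(v, transform = "log10")
  labels <- factor(ifelse(y == 1, "pos", "neg"), levels = c("neg", "pos"))
  fit <- fit_single_sample_model(qm, labels, c("a", "b", "c"), lambda = 1e-8)
  ref <- glm(y ~ scale(v[, "a"]) + scale(v[, "b"]) + scale(v[, "c"]),
             family = binomial())
  expect_equal(unname(c(fit$intercept, fit$w)), unname(coef(ref)), tolerance = 1e-4)
})

test_that("constant features are dropped and too-small intersections refused", {
  withr::with_seed(7, {
    v <- cbind(flat = rep(2, 30), a = rnorm(30, 3, .4), b = rnorm(30, 3, .4),
               c = rnorm(30, 3, .4))
    rownames(v) <- sprintf("s%02d", 1:30)
  })
  qm <- quant_matrix(v, transform = "log10")
  labels <- rep(c("A", "B"), 15)
  expect_warning(
    fit <- fit_single_sample_model(qm, labels, c("flat", "a", "b", "c")),
    "flat"
  )
  expect_false("flat" %in% fit$features)
  expect_error(
    suppressWarnings(fit_single_sample_model(qm, labels, c("flat", "a", "b"))),
    class = "adaptms_insufficient_features"
  )
})

setup_adaptive <- function(seed = 1, n_per_class = 40) {
  co <- toy_cohort(n_per_class = n_per_class, seed = seed)
  labels <- factor(co$metadata$class)
  rel <- build_relaxed_feature_set(co$matrix, labels, seed = seed + 1,
                                   n_requested = 20)
  refit <- prepare_refit_matrix(co$matrix, rel)
  list(co = co, labels = labels, rel = rel, refit = refit)
}

test_that("classification is bit-identical across repeated invocations", {
  st <- setup_adaptive(seed = 2)
  s <- as_sample_record(st$co$matrix, "S0005")
  runs <- lapply(1:10, function(i) {
    classify_sample(st$refit, st$labels, st$rel, s)$class_scores
  })
  for (i in 2:10) expect_identical(runs[[i]], runs[[1]])
})

test_that("a sample observing the full relaxed set equals the fixed-feature model exactly", {
  st <- setup_adaptive(seed = 3)
  fixed <- fit_nonrefit_logistic(st$refit, st$labels, colnames(st$refit$values))
  full_ids <- rownames(st$co$matrix$values)[
    rowSums(is.na(st$co$matrix$values[, st$rel$protein_id[st$rel$protein_id %in% colnames(st$co$matrix$values)], drop = FALSE])) == 0
  ]
  expect_gt(length(full_ids), 0)
  for (id in head(full_ids, 5)) {
    s <- as_sample_record(st$co$matrix, id)
    ad <- classify_sample(st$refit, st$labels, st$rel, s)
    nf <- non_refit_classify(fixed, s, fill_policy = "refuse")
    expect_identical(unname(ad$class_scores[2]), nf)
  }
})

test_that("results depend only on observed values over the intersection", {
  st <- setup_adaptive(seed = 4)
  s <- as_sample_record(st$co$matrix, "S0010")
  base <- classify_sample(st$refit, st$labels, st$rel, s)
  # perturb / add proteins outside the relaxed set: nothing may change
  extra <- s
  extra$quantified <- c(s$quantified, ZZZZ = 99)
  perturbed <- classify_sample(st$refit, st$labels, st$rel,
                               sample_record(extra$quantified, s$sample_id))
  expect_identical(base$class_scores, perturbed$class_scores)
  expect_identical(base$features_used, perturbed$features_used)
})

test_that("caching does not change any output", {
  st <- setup_adaptive(seed = 5)
  samples <- records_of(st$co$matrix)[1:10]
  cache <- new.env(parent = emptyenv())
  with_cache <- lapply(samples, function(s)
    classify_sample(st$refit, st$labels, st$rel, s, cache = cache)$class_scores)
  without <- lapply(samples, function(s)
    classify_sample(st$refit, st$labels, st$rel, s)$class_scores)
  expect_identical(with_cache, without)
})

test_that("one-vs-rest on three separated clusters recovers the middle class", {
  co <- generate_cohort(synthetic_config(
    n_per_class = c(25, 25, 25), n_proteins = 80, n_informative = 6,
    effect_size = 4, mnar_a = -10, seed = 17
  ))
  labels <- factor(co$metadata$class)
  rel <- build_relaxed_feature_set(co$matrix, labels, seed = 18, n_requested = 20)
  refit <- prepare_refit_matrix(co$matrix, rel)
  hits <- 0
  for (id in co$metadata$sample_id[co$metadata$class == "c2"][1:10]) {
    r <- classify_sample_multiclass(refit, labels, rel, as_sample_record(co$matrix, id))
    expect_equal(sum(r$class_scores), 1, tolerance = 1e-12)
    expect_true(all(r$class_scores >= 0 & r$class_scores <= 1))
    hits <- hits + (r$predicted_label == "c2")
  }
  expect_gte(hits, 9)
})

test_that("with two classes one-vs-rest agrees with the binary path", {
  st <- setup_adaptive(seed = 6, n_per_class = 25)
  for (id in rownames(st$co$matrix$values)[1:8]) {
    s <- as_sample_record(st$co$matrix, id)
    bin <- classify_sample(st$refit, st$labels, st$rel, s)
    ovr <- classify_sample_multiclass(st$refit, st$labels, st$rel, s)
    expect_equal(unname(ovr$class_scores), unname(bin$class_scores), tolerance = 1e-8)
    expect_identical(ovr$predicted_label, bin$predicted_label)
  }
})

test_that("batch classification is order-independent and isolates failures", {
  st <- setup_adaptive(seed = 7, n_per_class = 25)
  samples <- records_of(st$co$matrix)[1:6]
  bad <- sample_record(c(NOPE = 1), "zero_overlap")
  batch <- classify_batch(st$refit, st$labels, st$rel, c(samples, list(bad)))
  expect_equal(batch$status[7], "insufficient_overlap")
  expect_true(all(batch$status[1:6] == "ok"))
  expect_true(is.na(batch$score[7]))

  rev_batch <- classify_batch(st$refit, st$labels, st$rel, rev(c(samples, list(bad))))
  expect_identical(rev_batch$score, rev(batch$score))
  expect_identical(rev_batch$sample_id, rev(batch$sample_id))
})

test_that("adaptive results serialize to JSON and TSV", {
  st <- setup_adaptive(seed = 8, n_per_class = 25)
  batch <- classify_batch(st$refit, st$labels, st$rel, records_of(st$co$matrix)[1:3])
  json <- tempfile(fileext = ".json"); tsv <- tempfile(fileext = ".tsv")
  write_adaptive_results(batch, json, tsv_path = tsv)
  back <- jsonlite::read_json(json)
  expect_length(back, 3)
  expect_equal(back[[1]]$sample_id, batch$sample_id[1])
  expect_equal(sum(unlist(back[[1]]$class_scores)), 1, tolerance = 1e-12)
  expect_true(file.exists(tsv))
})
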