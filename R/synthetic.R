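#' Configure a synthetic proteomics cohort
#'
#' Generative parameters for cohorts with the statistical structure
#' discovery proteomics presents to a classifier: a minority of
#' class-informative proteins, log-normal intensities (Gaussian on the
#' log10 scale), abundance-dependent (MNAR) dropout so that low-abundance
#' proteins are missed more often, optional uniform (MCAR) dropout, and
#' optional per-site batch shifts.
#'
#' The dropout rule is `P(missing | x) = plogis(mnar_a - mnar_b * x)` on the
#' true log10 value `x`, with `mnar_b > 0` so lower abundance means higher
#' missingness. The defaults (`mnar_a = 2.6`, `mnar_b = 2`, baseline means
#' uniform on 0.5–5 log10 units, within-protein SD 0.25, `mcar_rate =
#' 0.01`) give roughly 20% overall missingness with a strong
#' abundance-missingness gradient.
#'
#' @param n_per_class Integer vector of per-class sample counts (length =
#'   number of classes; names become class labels, default "c1", "c2", ...).
#' @param n_proteins Total protein count.
#' @param n_informative Number of class-informative proteins
#'   (<= `n_proteins`).
#' @param effect_size Class mean shift on informative proteins, in units of
#'   `within_protein_sd`.
#' @param baseline_mean_range Interval the per-protein mean log10 abundance
#'   is drawn from.
#' @param within_protein_sd Within-protein (biological + technical) SD on
#'   the log10 scale.
#' @param mnar_a,mnar_b Offset and slope (> 0) of the MNAR dropout logistic.
#' @param mcar_rate Value-independent dropout fraction.
#' @param n_sites,site_effect_sd Number of sites and SD of the per-site,
#'   per-protein additive shift (0 = no batch effects). Each class
#'   contributes `n_per_class` samples at every site.
#' @param covariate_assoc Strength in \[0, 1\] of the association between the
#'   generated age/sex covariates and the class (0 = independent).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = c(100, 100), n_proteins = 1000,
                             n_informative = 20, effect_size = 1.5,
                             baseline_mean_range = c(0.5, 5),
                             within_protein_sd = 0.25,
                             mnar_a = 2.6, mnar_b = 2, mcar_rate = 0.01,
                             n_sites = 1, site_effect_sd = 0,
                             covariate_assoc = 0, seed = 1) {
  if (length(n_per_class) < 2) abort("At least two classes required.")
  if (any(n_per_class < 2)) abort("Every class needs at least two samples.")
  if (n_informative > n_proteins) abort("`n_informative` must not exceed `n_proteins`.")
  if (mnar_b <= 0) abort("`mnar_b` must be positive (lower abundance => more missingness).")
  if (mcar_rate < 0 || mcar_rate >= 1) abort("`mcar_rate` must be in [0, 1).")
  if (length(baseline_mean_range) != 2 || diff(baseline_mean_range) <= 0) {
    abort("`baseline_mean_range` must be an increasing interval.")
  }
  if (within_protein_sd <= 0) abort("`within_protein_sd` must be positive.")
  if (n_sites < 1) abort("`n_sites` must be at least 1.")
  if (covariate_assoc < 0 || covariate_assoc > 1) abort("`covariate_assoc` must be in [0, 1].")
  if (is.null(names(n_per_class))) {
    names(n_per_class) <- paste0("c", seq_along(n_per_class))
  }
  structure(list(
    n_per_class = n_per_class, k_classes = length(n_per_class),
    n_proteins = n_proteins, n_informative = n_informative,
    effect_size = effect_size, baseline_mean_range = baseline_mean_range,
    within_protein_sd = within_protein_sd,
    mnar_a = mnar_a, mnar_b = mnar_b, mcar_rate = mcar_rate,
    n_sites = n_sites, site_effect_sd = site_effect_sd,
    covariate_assoc = covariate_assoc, seed = seed
  ), class = "synthetic_config")
}

#' Generate a synthetic discovery cohort
#'
#' Draws per-protein baseline means, applies class shifts of
#' `effect_size * within_protein_sd` to the informative proteins (each
#' informative protein is assigned a target class — for two classes, the
#' second — and a random sign), adds Gaussian noise, then thins the complete
#' matrix by the MNAR rule followed by independent MCAR dropout. For
#' multi-site configs each site additionally receives its own per-protein
#' shift and a `site` metadata column.
#'
#' @param config A [synthetic_config()].
#' @return A list: `matrix` (log10-state [quant_matrix()]), `metadata`
#'   (tibble: sample_id, class, age, sex, and site when `n_sites > 1`),
#'   `ground_truth` (informative protein IDs, their target class and shift
#'   sign, and the complete pre-dropout matrix is NOT retained — only its
#'   generating parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    classes <- names(cfg$n_per_class)
    class_vec <- character(0); site_vec <- character(0)
    for (s in seq_len(cfg$n_sites)) {
      for (cl in classes) {
        class_vec <- c(class_vec, rep(cl, cfg$n_per_class[[cl]]))
        site_vec <- c(site_vec, rep(paste0("site", s), cfg$n_per_class[[cl]]))
      }
    }
    n <- length(class_vec)
    p <- cfg$n_proteins
    protein_id <- sprintf("P%04d", seq_len(p))
    sample_id <- sprintf("S%04d", seq_len(n))

    base_mean <- runif(p, cfg$baseline_mean_range[1], cfg$baseline_mean_range[2])
    informative <- sort(sample.int(p, cfg$n_informative))
    target_class <- classes[1 + (seq_along(informative) - 1) %% (cfg$k_classes - 1) + 1]
    # target class cycles over classes 2..k so each class has markers vs the rest
    shift_sign <- sample(c(-1, 1), cfg$n_informative, replace = TRUE)
    shift <- cfg$effect_size * cfg$within_protein_sd * shift_sign

    mu <- matrix(base_mean, nrow = n, ncol = p, byrow = TRUE)
    for (ii in seq_along(informative)) {
      rows <- class_vec == target_class[ii]
      mu[rows, informative[ii]] <- mu[rows, informative[ii]] + shift[ii]
    }
    if (cfg$n_sites > 1 && cfg$site_effect_sd > 0) {
      site_shift <- matrix(rnorm(cfg$n_sites * p, 0, cfg$site_effect_sd),
                           nrow = cfg$n_sites)
      mu <- mu + site_shift[as.integer(factor(site_vec, levels = paste0("site", seq_len(cfg$n_sites)))), ]
    }
    truth <- mu + matrix(rnorm(n * p, 0, cfg$within_protein_sd), n, p)

    p_miss <- stats::plogis(cfg$mnar_a - cfg$mnar_b * truth)
    drop_mnar <- matrix(runif(n * p), n, p) < p_miss
    drop_mcar <- matrix(runif(n * p), n, p) < cfg$mcar_rate
    values <- truth
    values[drop_mnar | drop_mcar] <- NA_real_
    # a sample with nothing observed cannot exist downstream; keep its
    # highest-abundance protein (vanishingly rare under the defaults)
    empty <- rowSums(!is.na(values)) == 0
    if (any(empty)) {
      j <- apply(truth[empty, , drop = FALSE], 1, which.max)
      values[cbind(which(empty), j)] <- truth[cbind(which(empty), j)]
    }
    dimnames(values) <- list(sample_id, protein_id)

    class_idx <- as.integer(factor(class_vec, levels = classes))
    age <- round(rnorm(n, 60 + cfg$covariate_assoc * 8 * (class_idx - mean(class_idx)), 10))
    p_female <- pmin(pmax(0.5 + cfg$covariate_assoc * 0.25 * (class_idx - mean(class_idx)), 0.05), 0.95)
    sex <- ifelse(rbinom(n, 1, p_female) == 1, "F", "M")

    metadata <- tibble::tibble(
      sample_id = sample_id, class = class_vec, age = age, sex = sex
    )
    if (cfg$n_sites > 1) metadata$site <- site_vec

    list(
      matrix = quant_matrix(values, transform = "log10"),
      metadata = metadata,
      ground_truth = list(
        informative = protein_id[informative],
        target_class = stats::setNames(target_class, protein_id[informative]),
        shift = stats::setNames(shift, protein_id[informative]),
        config = cfg
      )
    )
  })
}

#' @describeIn generate_cohort multi-site convenience wrapper; requires
#'   `n_sites >= 2` in the config.
#' @export
generate_multisite <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_sites < 2) abort("generate_multisite() needs a config with n_sites >= 2.")
  generate_cohort(config)
}

#' Per-protein abundance vs missingness profile
#'
#' QC table for the MNAR premise: per protein, the mean observed log10
#' abundance and the missing fraction. Under abundance-dependent dropout the
#' two are negatively rank-correlated.
#'
#' @param m A [quant_matrix()].
#' @return A tibble `protein_id`, `mean_observed`, `missing_fraction`,
#'   class `missingness_profile`.
#' @export
missingness_profile <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  v <- m$values
  obs <- !is.na(v)
  n_obs <- colSums(obs)
  v0 <- v; v0[!obs] <- 0
  out <- tibble::tibble(
    protein_id = colnames(v),
    mean_observed = ifelse(n_obs > 0, colSums(v0) / n_obs, NA_real_),
    missing_fraction = 1 - n_obs / nrow(v)
  )
  class(out) <- c("missingness_profile", class(out))
  out
}
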