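---
title: "Adaptive per-sample classification of discovery proteomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive per-sample classification of discovery proteomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptms)
```

## The problem

Untargeted (discovery) mass-spectrometry proteomics quantifies thousands of
proteins per sample, but not the *same* thousands in every sample:
low-abundance proteins drop out semi-stochastically, so the probability that
a protein is missing rises as its abundance falls. This missingness is
*missing not at random* (MNAR). A classifier trained once on a discovery
cohort and applied unchanged to new samples therefore faces incomplete
feature vectors, and the usual remedies — imputing the test sample, or
restricting to a small targeted panel — either fabricate values precisely
where the data are least trustworthy or discard most of the measurement.

`adaptms` takes the opposite route: the model adapts to the sample. From the
discovery cohort it builds a *relaxed* candidate feature list — deliberately
broader than any single selection run. For each test sample it intersects
that list with the proteins the sample actually quantified, retrains a small
logistic model de novo on the discovery data restricted to that
intersection, and scores the sample using only its measured values. No value
is ever imputed on the test side.

## The procedure

**1. Relaxed feature selection** (`build_relaxed_feature_set()`). For each of
`n_rounds` (default 10) rounds, a class-stratified random subset
(`subsample_frac`, default 80%, drawn without replacement) of the discovery
samples is tested protein by protein with a Welch (unequal-variance)
two-sample *t*-test on observed values only; *p*-values are
Benjamini–Hochberg adjusted across proteins and proteins with adjusted
*p* ≤ `alpha` (default 0.05) are selected. With three or more classes the
per-round test is the maximum over all pairwise Welch tests, adjusted within
each pair. Selections are aggregated into a per-protein selection frequency
and mean |t|; the top `n_requested` (default 50) proteins under
(frequency desc, mean |t| desc, ID asc) form the relaxed set. Subsampling
deliberately perturbs the cohort composition so the list does not hinge on
any particular subset of patients.

The Welch variant and Benjamini–Hochberg adjustment are deliberate choices:
protein-wise variances in plasma/CSF matrices are heteroscedastic, and BH is
the standard monotone step-up FDR procedure. Proteins with fewer than two
observations in a class are skipped in that round rather than imputed,
preserving the no-imputation principle end to end.

**2. Per-sample retraining** (`classify_sample()`). For a test sample $s$
with quantified set $Q(s)$, the custom feature set is
$F(s) = \text{relaxed} \cap Q(s)$, in relaxed order. On the discovery matrix
restricted to $F(s)$, an L2-regularized logistic regression

$$\hat\beta = \arg\min_\beta \; -\sum_i \big[y_i \log p_i + (1-y_i)\log(1-p_i)\big] + \tfrac{\lambda}{2}\lVert\beta_{-0}\rVert^2, \qquad p_i = \sigma(\beta_0 + z_i^\top \beta_{-0})$$

is fit by Newton iteration on features standardized with *training*
statistics (intercept unpenalized, $\lambda = 1$ by default, convergence
tolerance $10^{-6}$, zero start, step halving — a deterministic convex
solve). The sample is scored with its own log10 values under the same
standardization. The whole classification is a pure function of its inputs:
repeated calls are bit-identical, and a single classification carries no
confidence interval. With $k \ge 3$ classes, one one-vs-rest model is fit
per class and the positive scores are renormalized to sum to one
(argmax prediction, ties broken by label order).

If the intersection is empty the classification is *refused* with an
explicit insufficient-overlap signal — distinct from a low-confidence
score — and below `min_features` (default 3) usable features the fit is
likewise refused rather than guessed.

**3. Retrospective cohort matching** (`match_cohort()`, `run_task()`). When a
proteome database with metadata is available, a task-specific training
cohort is sliced per query patient: hard constraints per covariate
(categorical exact match, continuous closed window such as age ± years),
optional label recoding, optional downsampling to the minority class with a
recorded seed, and the query patient always excluded. Windowed hard
constraints were chosen over propensity or distance weighting: they are
simple, auditable, and match the slice-and-match framing; the matching
report records per-constraint exclusion counts. One measured sample can then
answer several diagnostic questions without re-acquisition.

## Training-side missingness: a deliberate design choice

The per-sample refit needs complete training values on the intersected
features. Two cohort-level tools exist: `filter_completeness()` removes
proteins missing in more than 5% of samples (strict inequality), and
`knn_impute()` fills the remainder (k = 5; Euclidean distance over mutually
observed proteins, rescaled by the fraction of coordinates used so sparsity
does not shrink distances; ties broken by sample order; observed values
never altered).

For the **fixed-feature baselines** (`prepare_training()`,
`fit_fixed_pipeline()`) both are applied as stated: filter at 5%, impute
once, then random-forest importance ranking followed by gradient boosting.

For the **adaptive path** the 5% filter would be self-defeating under
realistic MNAR: with ~20% overall abundance-dependent missingness roughly
half the proteome — disproportionately the lower-abundance half, where
informative proteins may live — exceeds a 5% missingness threshold. The
adaptive architecture exists precisely to use such proteins in the samples
that measured them. Relaxed selection therefore runs on the unfiltered
matrix (its pairwise-complete tests need no completeness), and the one-time
KNN imputation (`prepare_refit_matrix()`) is applied to the training matrix
*restricted to the relaxed features*, all of which were testable and hence
well observed. A training sample observing none of the relaxed features
carries no neighbour information and is mean-filled with a warning. Test
samples are never imputed; a perturbation test asserts that predictions
depend only on observed values over the intersection.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the method assumes,
so every stage is testable without downloads:

* **Intensities.** Per-protein mean log10 abundance uniform on 0.5–5 (raw
  intensities span ~3–100,000), within-protein Gaussian noise with SD 0.25
  on the log10 scale — a log-normal intensity model, standard for MS
  matrices.
* **Class structure.** `n_informative` of `n_proteins` proteins receive a
  mean shift of `effect_size` × SD in a target class (random sign; with
  k > 2 classes the target cycles over classes so each has markers).
* **Missingness.** MNAR acts on the true value before observation:
  $P(\text{missing}\mid x) = \mathrm{plogis}(a - b x)$ with $b = 2 > 0$
  (lower abundance ⇒ more dropout) and $a = 2.6$, set from the closed-form
  integral of the logistic over the abundance range to give ~20% overall
  missingness with a strong abundance gradient (Spearman correlation between
  abundance and missing fraction ≈ −0.96). Independent MCAR dropout
  (default 1%) follows.
* **Sites and covariates.** Optional per-site additive protein-wise shifts
  (SD `site_effect_sd`) emulate cohort-specific batch signatures; age/sex
  covariates can be confounded with class via `covariate_assoc` to exercise
  cohort matching.

What the generator does **not** emulate: peptide-level quantification and
roll-up, correlated protein modules, heavy-tailed or intensity-dependent
noise, interference/FDR artefacts, and real instrument drift. Passing tests
on these cohorts demonstrate the architecture's statistical behaviour under
its stated assumptions, not clinical performance on real data.

## Evaluation harness

`roc_auc()` computes AUC as the Mann–Whitney pairwise-concordance statistic
(ties ½, via midranks) and the ROC by threshold sweep. `repeated_cv()` runs
stratified 5-fold cross-validation repeated 10 times; the *entire* pipeline
— selection and any imputation included — is refit inside each training
fold, so no information leaks into held-out folds (a test demonstrates the
AUC inflation that out-of-fold selection would cause). Confidence intervals
are 2.5/97.5 percentiles over repeats — the convention chosen for
repetition-based shading; a single adaptive classification is deterministic
and carries none. `learning_curve()`, `cross_site_eval()` and
`feature_usage_summary()` (boxplot statistics of per-sample feature counts,
split by correctness at the 0.5 threshold / argmax) complete the harness,
each with an `autoplot()` method.

## Numerical and degenerate-input conventions

* Raw intensities ≤ 0 and blank/NaN cells are missing at read time;
  log10 transformation refuses anything else non-positive.
* A protein constant and equal in both classes gets t = 0, p = 1; constant
  but unequal gets infinite |t|, p = 0.
* Equidistant imputation neighbours and tied class scores are resolved by
  stable (index / label) order — all outputs are deterministic.
* If no feature passes `alpha` in any round, selection fails loudly and
  suggests either raising `alpha` or `fallback = "rank"` (top `n_requested`
  by |t| per round); the evaluation harness uses the rank fallback so null
  cohorts still produce (noise) feature sets and calibrate at AUC ≈ 0.5.
* Refit models are cached per distinct feature tuple inside a batch;
  caching is contractually output-invariant and covered by a test.

## Problem sizes used in the shipped tests

The test suite and acceptance script run entirely on generated cohorts at
desk scale, chosen once: null calibration at 200 samples × 1000 proteins
with 5×10 repeated CV; planted-signal recovery and baseline comparisons on
cohorts of 200/class split in half (train 100/class), 1000 proteins, 20
informative at 1.5 SD, ten seeds; learning curves at training sizes
50–400; feature-count plateau at 10/50/200 requested features. For the
cross-site study the conditions were set off the AUC ceiling so the
directional effects are measurable: 60/class/site at three sites, 10
informative proteins at 1.2 SD, site-effect SD 0.7 (≈2.8× the
within-protein SD) — giving within-site AUC ≈ 0.96 against cross-site
≈ 0.8, with pooled multi-site training recovering most of the weakest
site's loss.

## Known limitations

* Only linear logistic models run in the adaptive path; the architecture is
  agnostic to the classifier, and tree ensembles appear as fixed-feature
  baselines only.
* Protein identifiers are opaque strings; no isoform collapsing or cross-
  cohort ID reconciliation is attempted.
* Cohort matching is hard-windowed; no propensity scores, optimal matching
  or nearest-neighbour comparators.
* The per-sample refit assumes the discovery cohort is exchangeable with
  the test sample's population; covariate shift is addressed only through
  explicit cohort matching, not through reweighting.

## A minimal run

```{r example, eval = FALSE}
co <- generate_cohort(synthetic_config(seed = 42))
labels <- factor(co$metadata$class)

relaxed <- build_relaxed_feature_set(co$matrix, labels, seed = 7)
refit <- prepare_refit_matrix(co$matrix, relaxed)

s <- as_sample_record(co$matrix, "S0003")
res <- classify_sample(refit, labels, relaxed, s)
tidy(res)

rep <- repeated_cv(co$matrix, labels, n_repeats = 10, seed = 1)
glance(rep)
autoplot(rep)
```
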