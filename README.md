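# adaptms

Diagnostic classification of *individual* discovery-proteomics samples,
without test-side imputation.

Untargeted mass spectrometry quantifies thousands of proteins per sample,
but low-abundance proteins drop out semi-stochastically — missingness that
depends on the (unobserved) value itself (MNAR). A classifier trained once
on a discovery cohort and applied unchanged to new patients therefore sees
incomplete feature vectors and either needs imputation exactly where the
data are least trustworthy, or a narrow targeted panel that discards most
of the proteome.

`adaptms` instead adapts the model to each sample:

1. **Relaxed feature selection.** From the discovery cohort, repeated
   class-stratified subsampling (default 10 rounds of 80%) with per-protein
   Welch *t*-tests on observed values only, Benjamini–Hochberg adjusted
   (α = 0.05); selections are aggregated by frequency and mean |t| into a
   candidate list of up to `n_requested` proteins (default 50) —
   deliberately broader than any single selection run.
2. **Per-sample retraining.** For a test sample with quantified set *Q*, a
   ridge logistic model

   minimize −Σᵢ [yᵢ log pᵢ + (1−yᵢ) log(1−pᵢ)] + (λ/2)‖β‖²,  pᵢ = σ(β₀ + zᵢᵀβ)

   is refit de novo on the discovery data restricted to
   *relaxed ∩ Q* (training-statistics standardization, λ = 1, intercept
   unpenalized, deterministic Newton solve), and the sample is scored from
   its own measured log10 intensities only. Multiclass tasks use one
   one-vs-rest model per class with renormalized scores.
3. **Retrospective cohort matching.** Given a proteome database with
   metadata, a covariate-matched training cohort (exact categorical match,
   closed windows for continuous covariates such as age ± years) is sliced
   per query patient, so one measured sample can answer several diagnostic
   questions.

Fixed-feature baselines (random-forest ranking + gradient boosting on a
5%-completeness-filtered, KNN-imputed matrix; non-refit logistic with
zero/mean fill), a synthetic cohort generator with abundance-dependent
dropout and multi-site batch effects, and an evaluation harness (repeated
stratified CV, learning curves, cross-site evaluation, per-sample
feature-usage diagnostics) round out the package. Who it is for: developers
of MS-based diagnostic classifiers who want to validate and deploy on
single samples as they arrive, without panel lock-in or full-matrix
harmonization.

## Worked example

```r
library(adaptms)

co <- generate_cohort(synthetic_config(seed = 42))   # 100/class, 1000 proteins,
labels <- factor(co$metadata$class)                  # 20 informative, MNAR dropout
co$matrix
#> <quant_matrix> 200 samples x 1000 proteins (log10 scale), 21.9% missing

relaxed <- build_relaxed_feature_set(co$matrix, labels, seed = 7)
relaxed
#> <relaxed_feature_set> 26 features (binary task; 10 rounds x 80% subsamples, alpha = 0.05)
#> # A tibble: 26 × 3
#>   protein_id selection_frequency mean_abs_stat
#>   <chr>                    <dbl>         <dbl>
#> 1 P0474                        1          11.1
#> 2 P0106                        1          10.2
#> ...

refit <- prepare_refit_matrix(co$matrix, relaxed)    # one-time training completion
s <- as_sample_record(co$matrix, "S0003")
s
#> <sample_record> S0003: 773 quantified proteins

classify_sample(refit, labels, relaxed, s) |> glance()
#> # A tibble: 1 × 4
#>   sample_id predicted_label top_score n_features_used
#>   <chr>     <chr>               <dbl>           <int>
#> 1 S0003     c1                  0.997              20
```

The sample quantified 773 of 1000 proteins; 20 of the 26 relaxed features
were among them, a fresh model was trained on exactly those 20, and the
sample is called class `c1` (its true class) with probability 0.997. A
sample sharing no protein with the relaxed list is *refused* with an
explicit insufficient-overlap signal rather than scored. The same call is
bit-identical on every invocation — single-sample classifications are
deterministic and carry no confidence interval.

Cohort-level evaluation follows the same grammar:

```r
rep <- repeated_cv(co$matrix, labels, n_folds = 5, n_repeats = 10, seed = 1)
glance(rep)    # mean AUC with a percentile CI over repeats
autoplot(rep)  # ROC
```

A thin command-line wrapper over the same functions ships at
`inst/scripts/adaptms.R` (subcommands `simulate`, `build-features`,
`classify`, `evaluate`).

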