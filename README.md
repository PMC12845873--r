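# eegfuse

Feature-level fusion of EEG **microstate** dynamics and **empirical mode
decomposition (EMD)** statistics for classifying schizophrenia and symptom
severity from resting-state recordings — with a synthetic EEG cohort
generator that provides full ground truth, so the whole pipeline is
testable end-to-end without clinical data.

It is aimed at researchers in EEG-based computational psychiatry who want a
reproducible, inspectable implementation of the microstate + EMD fusion
approach: signal in (EDF or delimited matrices), per-subject feature
vectors, cross-validated classification metrics, and per-feature Shapley
attributions out.

## The method

For each subject:

1. **Preprocess** — band-pass 0.1–40 Hz, 50 Hz notch (zero-phase
   Butterworth), resample to 250 Hz, bilateral-mastoid re-reference, keep
   the 17 analysis channels.
2. **Microstate block (W, 24 features)** — global field power
   `GFP_n = sqrt(Σ_i (x_in − x̄_n)² / N)`; 1000 GFP-peak topographies per
   subject pooled and clustered into K = 4 classes (A–D) by
   polarity-invariant modified K-means (assignment by maximal squared
   spatial correlation, templates re-estimated as first principal
   components, best of 50 restarts by global explained variance); every
   sample backfit to its best template; per class: mean duration,
   occurrence, coverage, plus the 12 transition probabilities.
3. **EMD block (E)** — per channel, classic sifting (cubic-spline
   envelopes, Cauchy stopping criterion 0.2) standardized to 9 IMFs, 14
   statistics per IMF: a 17 × 9 × 14 tensor, 2142 features.
4. **Fusion** — `R = [W | E_avg]` where `E_avg[i,k] = (1/M) Σ_j e[i,j,k]`
   averages the tensor over the IMF axis: 24 + 17 × 14 = **262 features**,
   named `f1..f24` (microstate) and `f25..` (EMD).
5. **Classify** — inside each fold of subject-wise stratified 10-fold CV:
   z-score on the training fold, LASSO selection
   (`min (1/2n) Σ (y_i − ω'x_i)² + λ‖ω‖₁`, λ by inner CV), logistic /
   multinomial-softmax regression with TPE-tuned inverse-regularization
   strength; report AUC / ACC / SPE / SEN with 95% CIs and pooled
   confusion matrices.
6. **Explain** — exact linear Shapley values `φ_i = w_i (x_i − μ_i)` per
   class on held-out subjects; global importance and the
   microstate-vs-EMD modality split.

See `vignettes/feature-fusion.Rmd` for the full methods account, all
tunable parameters, and known limitations.

## Worked example

Simulate a 2 × 8-subject cohort (30 s per subject) with the default
planted contrast — the patient group has an elevated B→D transition
probability, a longer class-A duration and stronger slow drift — then
extract, fuse, cross-validate and explain:

```r
library(eegfuse)

spec   <- default_cohort_spec(n_per_group = 8, duration = 30)
cohort <- generate_cohort(spec, seed = 1)
feats  <- extract_features(cohort$recordings, n_peaks = 500,
                           n_restarts = 20, seed = 1)
fm     <- build_feature_matrix(feats$subjects, mode = "fused")
dim(fm$X)
#> [1]  16 262

cv <- run_cv(fm, k = 8, n_repeats = 2, seed = 1, budget = 10)
cv
#> <cv_result> mode=fused, 16 fold-evaluations
#>      mean    lo    hi
#> AUC 0.938 0.764 1.111
#> ACC 0.875 0.720 1.030
#> SPE 1.000 1.000 1.000
#> SEN 0.750 0.440 1.060

ex <- explain_cv(cv, fm)
head(global_importance(ex, "SCZ"), 3)
#>   feature importance rank
#> 1    f197  0.7592888    1
#> 2     f72  0.6065074    2
#> 3     f71  0.4540292    3
```

The CV table reads as in clinical reports: with 16 subjects the fused
features separate the groups almost perfectly (AUC 0.94), specificity 1
means no control was called a patient, and the wide CIs reflect the small
fold size. The top attributed features here are EMD statistics (`f197`,
`f72` — drift-sensitive channel statistics), consistent with the strong
planted drift difference; with a microstate-only contrast the top features
are microstate parameters instead (that property is asserted in the test
suite). Larger cohorts (e.g. `n_per_group = 16`, `duration = 60`) reach
AUC 1.0 — see the acceptance script below.

A thin CLI wraps the same stages:

```sh
Rscript inst/cli/eegfuse.R run-all --out out/ --seed 1 --n-per-group 8
```

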