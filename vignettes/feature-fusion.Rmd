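---
title: "Microstate + EMD feature fusion for EEG classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate + EMD feature fusion for EEG classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegfuse)
```

## The problem

Resting-state EEG carries two complementary kinds of information about
psychiatric conditions such as schizophrenia. The *spatial-dynamic* side is
captured by **microstates**: brief (~50–120 ms) epochs during which the
scalp topography stays quasi-stable, conventionally reduced to four
canonical classes A–D. Patients differ from controls in how long each class
lasts, how often it occurs, and how classes follow one another. The
*nonlinear, nonstationary* side is captured by **empirical mode
decomposition (EMD)**, which adaptively splits each channel into intrinsic
mode functions (IMFs) whose amplitude statistics reflect spectral and
envelope structure that fixed-band filters miss.

`eegfuse` implements a feature-level fusion of the two: 24 microstate
parameters are concatenated with IMF-averaged per-channel statistics into
one fused vector per subject, which feeds a LASSO-then-logistic-regression
classifier evaluated with subject-wise cross-validation, and is explained
with exact Shapley attributions. Because clinical EEG is rarely shareable,
the package ships a synthetic cohort generator with full ground truth, so
every stage can be validated end-to-end.

## Pipeline and models

### Preprocessing

Recordings (EDF or delimited matrices, channels × samples) are band-pass
filtered 0.1–40 Hz with a 50 Hz notch, resampled to 250 Hz, re-referenced
to the bilateral mastoids, and reduced to the 17 analysis channels by
dropping the mastoid channels. The filter family is a package choice (the
underlying method fixes only the passband): zero-phase forward–backward
Butterworth, 2nd-order high-pass, 4th-order low-pass, 2nd-order band-stop
±2 Hz around the mains frequency. Zero-phase filtering matters here because
a latency shift would systematically bias microstate segment boundaries.
Seventeen-channel input without mastoids passes through re-referencing
unchanged (with a notice), so purely synthetic data uses the same code
path.

### Microstate stage

For each subject the global field power
\(\mathrm{GFP}_n = \sqrt{\sum_i (x_{in}-\bar x_n)^2 / N}\)
is computed per sample; 1000 topographies at strict GFP local maxima are
sampled per subject and pooled over subjects. The pooled maps are clustered
with a **polarity-invariant modified K-means**: maps are assigned by
maximal squared spatial correlation (sign ignored) and each template is
re-estimated as the first principal component of its assigned maps; the
best of 50 random restarts by global explained variance (GEV) is kept
(convergence tolerance 1e-6, iteration cap 300). Plain Euclidean K-means
would split every class into a ± pair, because microstate topographies are
sign-ambiguous; polarity invariance is the field's standard resolution and
is used here deliberately.

Clusters are ordered into A–D by greedy one-to-one matching against
built-in canonical reference maps (diagonal, mirrored-diagonal,
anterior–posterior, and fronto-central focal patterns on 10–20
coordinates); non-standard channel sets fall back to the clustering order
with a notice. Every sample of every recording is then *backfit* to its
best template — again by squared correlation, with **no temporal
smoothing** (none is part of the method being implemented), zero-variance
samples inheriting the previous label.

From the per-sample labels we compute, per class: mean segment duration
(ms), occurrences (segments/s), and time coverage (fraction), plus the 12
ordered transition probabilities — 24 features named `f1`–`f24` in the
order: durations A–D, occurrences A–D, coverages A–D, transitions row-major
(A→B, A→C, A→D, B→A, …, D→C). The numbering of the transition block is a
frozen package convention; published per-feature labels in this literature
are not always mutually consistent, so the mapping from `f`-numbers to
descriptive names is always carried in the `feature_names` attribute and in
all written tables.

Group templates are clustered once on maps pooled over **all** subjects.
This mirrors the group-template convention of microstate analysis and is
label-free: no class information enters the clustering, so it cannot leak
group structure into held-out folds. All label-dependent statistics
(standardization, selection, tuning) are computed strictly within training
folds.

### EMD stage

Each channel is decomposed by classic sifting: cubic-spline upper/lower
envelopes through the extrema (mirror-extending two extrema per side to
suppress end swings), envelope-mean subtraction until the Cauchy criterion
\( \sum (h_{prev}-h)^2 / \sum h_{prev}^2 < 0.2 \) (or 100 sift iterations),
peeling IMFs until the residual has fewer than two extrema or 12 IMFs.
Reconstruction \(\sum \mathrm{IMF}_j + r = x\) holds to machine precision by
construction and is asserted in the tests.

IMF counts vary between subjects, so each channel is standardized to the
**first nine** IMFs (the high-frequency ones, which carry the oscillatory
content); a shortfall pads with zero signals rather than erroring, keeping
degenerate synthetic inputs runnable. Fourteen statistics are computed per
IMF: mean, max, min, Q1, Q3, IQR, median, population variance, population
SD, excess kurtosis, skewness, RMS, Hjorth activity, and peak-to-peak
range. Two conventions to note: skewness/kurtosis of a zero-variance signal
are defined as 0, and Hjorth activity *is* the signal variance — it is kept
as a separate slot because the fourteen-statistic layout is part of the
method's feature arithmetic (17 × 9 × 14 = 2142). The identity of the
fourteenth statistic is ambiguous in the source literature; peak-to-peak
range was chosen and frozen.

### Fusion

The 17 × 9 × 14 tensor is averaged over the IMF axis (positions preserved)
to a 17 × 14 matrix, flattened channel-major, and concatenated after the 24
microstate features: 24 + 238 = 262 features, named `f25` onward. No
scaling happens at fusion time — z-scoring is deferred to the training fold
of each CV split to avoid leakage.

### Selection, classification, tuning

Feature selection minimizes the L1-penalized squared loss
\(\tfrac1{2n}\sum_i (y_i - \omega^\top x_i)^2 + \lambda\lVert\omega\rVert_1\)
on the z-scored training fold with numeric-encoded labels, with λ chosen by
inner 5-fold CV over 30 log-spaced values in [1e-4, 10]. Three-class
problems run one-vs-rest and union the supports. If everything shrinks to
zero the single best-correlated feature is kept and flagged. The engine is
`glmnet` coordinate descent; with `standardize = FALSE, intercept = FALSE`
its objective is exactly the expression above, which the test suite pins to
the closed-form soft-threshold solution on orthonormal designs.

The classifier is (multinomial) logistic regression — softmax for three
classes — with ridge-regularized likelihood, the inverse-regularization
strength C tuned per fold by a compact seeded **tree-structured Parzen
estimator** over log C ∈ [log 1e-3, log 1e3]: uniform startup trials, then
candidates sampled from a Gaussian kernel density over the top-quartile
trials and scored by the good/bad density ratio; the objective is mean
inner 3-fold CV accuracy. Whether to tune or fix the penalty was an open
choice; tuning inside the fold was chosen because it is the leakage-safe
default.

Evaluation uses subject-wise stratified 10-fold CV (a subject's data is
never split across train and test), repeated with derived seeds; AUC, ACC,
SPE, SEN are averaged over folds with a normal-approximation 95% CI
(mean ± 1.96·SD/√k over fold metrics). The positive class for binary
SPE/SEN is the patient group. The CI procedure is a documented package
choice.

### Attribution

Because the fitted model is linear in the (standardized, selected)
features, exact Shapley values under feature independence have the closed
form \(\phi_i = w_i (x_i - \mu_i)\) on the margin scale, with base value
\(w^\top\mu + b\) at the training-mean background. This is exact — local
accuracy (base + Σ attributions = margin) holds to machine precision and is
asserted at 1e-10 — fast, and reproducible, which is why it is used instead
of sampling-based kernel approximations. Explanations are computed on
held-out subjects with each fold's model and pooled; global importance is
mean |attribution| per feature, and the modality split (f1–f24 vs f25+)
summarizes how much each block contributes per class.

## The synthetic generator

Each subject is a semi-Markov chain over K = 4 shared topographic
templates: segment classes follow a row-stochastic transition matrix with
zero diagonal, segment lengths are gamma(shape 2) with the requested
per-class mean (80 ms default; gamma avoids sub-sample segments and has a
realistic coefficient of variation), and the active template is multiplied
by a 10 Hz carrier — so the GFP peaks twice per alpha cycle, as in real
resting EEG. On top go a slow (0.1 Hz) additive drift with a fixed random
topography, and noise that is 70% spatially white / 30% per-channel
1/f-shaped, jointly scaled to the requested signal-to-noise power ratio
(default 4). Templates are zero-mean, unit-norm, mutually orthogonal
channel vectors, shared by the whole cohort — only the dynamics and drift
differ between groups, which is what makes the planted contrasts
identifiable.

The default two-group cohort plants the direction of reported microstate
abnormalities: the patient group has B→D transition probability 0.6 (vs the
uniform 1/3), class-A mean duration 120 ms (vs 80 ms), and drift amplitude
1.0 (vs 0.3) so the EMD block also separates groups. The three-class
variant adds an intermediate "mild" group. These values are frozen; they
were chosen to be plainly super-threshold for a 2 × 16-subject design, not
calibrated against any test outcome.

What the generator does *not* emulate: volume-conducted source geometry,
eye/muscle artifacts, heteroscedastic channel noise, inter-subject montage
variation, or non-Markovian syntax in state sequences. Passing tests
therefore demonstrate that the pipeline recovers known structure of this
generative family — not clinical validity on real recordings.

## Numerical choices and degenerate inputs

- GFP peaks are *strict* local maxima; constant series have none.
- Fewer available peaks than requested samples all of them with a notice.
- Empty clusters keep their previous template; GEV is monotone within a
  restart (both K-means steps are ascent steps, asserted in tests).
- Zero-variance samples in backfitting inherit the previous label.
- A class absent from a segmentation contributes zeros to all four
  parameter families; outgoing transition rows normalize only over
  segments that have a successor, so coverage = occurrence × mean duration
  holds exactly.
- Constant columns are dropped before selection with a warning; a
  single-feature model is padded with a null column for the fitting
  backend and the pad is stripped from all coefficient reads.
- EDF round-trips are exact up to the 16-bit quantization of each
  channel's physical range.

## Problem sizes

Test and acceptance runs use sizes chosen to exercise every code path at
desk scale: 60 s recordings for feature-dimension and cohort runs (the
microstate label-recovery check uses a single 5-minute subject, where the
empirical transition matrix of an 80 ms-segment chain converges to within
0.05 of its generator), 2 × 16 subjects for the planted-contrast
classification, 2 × 10 for the null cohort, and 2 CV repetitions
(`run_cv()` defaults to 10). The 15-minute recordings and ~30–124-subject
cohorts typical of clinical studies run through exactly the same code,
only slower.

## Known limitations

- Backfit segment durations are biased short in noise: without temporal
  smoothing, isolated misassigned samples split segments. At SNR 4 a
  90%-accurate labelling turns 80 ms true segments into ~20 ms observed
  ones. Duration/transition *recovery* is therefore validated on the
  ground-truth sequence, and between-group *contrasts* in the flicker-robust
  features (coverage, occurrence) are what the classifier exploits. Apply
  duration estimates from this pipeline to real data with that bias in
  mind.
- The canonical A–D reference maps are idealized geometric patterns, not
  empirical grand averages; they fix a consistent ordering rather than
  anatomical truth.
- Three-class LASSO uses one-vs-rest support unions; a grouped multinomial
  penalty would select differently.
- The EMD stage runs on the full continuous signal per channel; very long
  recordings pay O(n log n)-ish spline costs per sift iteration.
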