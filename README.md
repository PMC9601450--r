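# pnesentropy

Entropy-based analysis of interictal EEG and ECG for differentiating
psychogenic non-epileptic seizures (PNES) from epilepsy.

PNES resemble epileptic seizures clinically but involve no epileptiform
brain activity, and the gold-standard video-EEG diagnosis is costly and
slow. This package implements, as a tested R pipeline, an analysis that
asks whether resting-state (interictal) scalp EEG plus a single derived
ECG lead already separate the two conditions: entropy features per channel
and frequency band, machine-learning classification under class imbalance,
and a band-level attribution experiment. It is aimed at biomedical
signal-analysis researchers who want each stage — synthetic data,
preprocessing, estimators, classification, importance — as an inspectable,
reusable component.

## Method

For each 10-s epoch (N = 2560 samples at 256 Hz), each of 21 channels
(20 EEG + derived ECG), and each frequency band (broad 0.5–40 Hz, delta
0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–40 Hz), six entropy
statistics are computed:

- approximate entropy ApEn(m, r) = Φ^m(r) − Φ^(m+1)(r), with Φ^m the mean
  ln fraction of length-m templates within Chebyshev tolerance r
  (self-matches included);
- sample entropy SampEn(m, r) = −ln(A^m(r) / B^m(r)) (self-matches
  excluded), with r = r_sd·SD per epoch and (m, r_sd) selectable by a
  grid-search protocol over {1, 2} × {0.1, 0.15, 0.2, 0.25};
- spectral entropy −(1/ln Ω) Σᵢ pᵢ ln pᵢ over the normalized Welch PSD;
- SVD entropy −(1/log₂ L) Σₗ pₗ log₂ pₗ over normalized squared singular
  values of the delay-embedding matrix;
- Rényi entropy (1/(1−α)) log₂ Σᵢ pᵢ^α (α = 2) of the amplitude histogram;
- wavelet entropy −Σⱼ pⱼ ln pⱼ over relative Morlet scale energies.

Features feed four classifiers (RBF-SVM with γ = 1/(p·Var), kNN with inner
k-search, random forest, gradient boosting) under stratified epoch-wise
10-fold cross-validation with per-fold z-scoring, SMOTE oversampling of the
minority class, and PCA to 95% explained variance; performance is measured
by precision, recall, and balanced accuracy = ½(TP/(TP+FN) + TN/(TN+FP)),
with PNES as the positive class. Band relevance is assessed by grouped
permutation importance, i = s − (1/K) Σₖ s̃ₖ (all 21 columns of a band
shuffled jointly), and by a band-exclusion experiment.

The clinical recordings behind the original analysis are not publicly
available, so the package includes a synthetic cohort generator
(`generate_cohort()`) that plants a configurable, entropy-visible class
contrast (band-limited oscillation amplitude, optional spectral-exponent
difference, ECG beat-timing jitter) inside an EEG-like 1/f background —
every downstream stage runs and is tested against it. See the methods
vignette (`vignettes/entropy-pipeline.Rmd`) for assumptions and design
choices.

## Worked example

```r
library(pnesentropy)

cfg <- cohort_config(n_per_class = c(PNES = 10, epilepsy = 10),
                     epochs_per_subject = 20, seed = 1)
cohort <- generate_cohort(cfg)          # 20 subjects, 21 channels each
pre    <- preprocess_cohort(cohort)     # filter, epoch, reject, bands
feats  <- extract_features(pre$bands, "renyi")
cv     <- run_cv(feats, classifier_spec("knn"), folds = 10, seed = 1)
cv
#> <cv_result> knn | renyi | bands: broad,delta,theta,alpha,beta,gamma
#>   10-fold CV: bal.acc 1.0000, precision 1.0000, recall 1.0000
```

The generator's default theta-band contrast is strong, so the combined
six-band Rényi features separate the two synthetic classes essentially
perfectly; with `contrast = 0` the same pipeline returns chance-level
balanced accuracy (~0.5). Band attribution over the five disjoint narrow
bands recovers the planted band:

```r
fm5  <- extract_features(pre$bands[c("delta","theta","alpha","beta","gamma")], "renyi")
excl <- band_exclusion_experiment(fm5, classifier_spec("knn"),
                                  folds = 10, K = 10, seed = 1)
excl[, c("band_excluded", "balanced_accuracy", "band_importance")]
#>   band_excluded balanced_accuracy band_importance
#> 1         delta         0.9976190    0.0223809524
#> 2         theta         0.6285714    0.3088095238
#> 3         alpha         0.9976190   -0.0033333333
#> 4          beta         0.9928571    0.0007142857
#> 5         gamma         0.9976190   -0.0028571429
#> 6          none         0.9880952              NA
```

Excluding the planted theta band collapses the accuracy, and theta's
permutation importance dominates; the remaining bands contribute at most
a small residual (delta's upper filter transition reaches the 6 Hz
oscillation), as designed.

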