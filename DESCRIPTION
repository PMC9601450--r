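Package: pnesentropy
Title: Entropy-Based Interictal EEG/ECG Analysis for Psychogenic
    Non-Epileptic Seizures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for differentiating psychogenic non-epileptic
    seizures (PNES) from epilepsy using entropy features of interictal
    scalp EEG and a derived single-lead ECG.  Provides a synthetic cohort
    generator with configurable class contrast, EDF 16-bit input/output,
    a signal-conditioning chain (resampling, zero-phase FIR/Bessel
    filtering, epoching, amplitude-based artifact rejection, per-subject
    baseline correction, frequency-band decomposition), six entropy
    estimators (approximate, sample, spectral, singular value
    decomposition, Renyi, and wavelet entropy), an (m, r) grid-search
    protocol for the template entropies, imbalance-aware cross-validated
    classification (SMOTE oversampling, PCA to 95% variance, RBF-SVM,
    k-nearest neighbours, random forest, gradient boosting), and grouped
    permutation importance of frequency bands with a band-exclusion
    experiment.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    randomForest,
    signal,
    stats,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
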