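---
title: "Entropy-based interictal EEG/ECG analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based interictal EEG/ECG analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Psychogenic non-epileptic seizures (PNES) clinically resemble epileptic
seizures but are not driven by epileptiform brain activity, and they are
frequently misdiagnosed — the gold-standard video-EEG work-up is expensive
and not universally available. A candidate low-cost screen is to ask
whether *interictal* (between-seizure, resting) surface EEG and ECG already
carry class information, quantified by entropy: statistics that score the
irregularity or spectral disorder of a signal. This package implements
that analysis as a reusable, tested pipeline: six entropy estimators per
channel per frequency band, imbalance-aware cross-validated classification,
and grouped permutation importance of the frequency bands.

Because the clinical recordings that motivated the pipeline are not
redistributable, the package ships a synthetic cohort generator that
reproduces the *statistical structure* the analysis relies on, so that every
stage is exercisable and testable without any external data.

## Signal conditioning

The preprocessing chain mirrors standard clinical-EEG practice:

1. **Resampling** to 256 Hz (anti-aliased zero-phase FIR decimation from
   512 or 1024 Hz) and restriction to the common 10–20 montage:
   20 scalp electrodes plus the two ECG leads.
2. **Broad-band filtering** of the EEG at 0.5–40 Hz with a Hamming-window
   FIR filter.
3. **ECG derivation**: the single ECG channel is (ECG+) − (ECG−), band-passed
   0.25–40 Hz with a Bessel IIR filter and high-passed at 0.05 Hz for
   baseline wander. The same derived ECG accompanies every EEG band.
4. **Epoching** into non-overlapping 10-s epochs (2560 samples), dropping
   trailing partial data.
5. **Artifact rejection** by amplitude criteria: flat epochs (every EEG
   channel's peak-to-peak below 1 µV), noisy epochs (any channel's
   peak-to-peak above a configurable ceiling, 300 µV by default), and
   flat-ECG epochs. The noisy-epoch rule is a deliberate, configurable
   stand-in for consensus-threshold rejection algorithms, whose internals
   are out of scope; the flat-ECG rule replaces visual inspection. The 1 µV
   flatness criterion is interpreted as peak-to-peak (configurable), since
   an absolute-maximum reading would also reject well-centred signals.
6. **Baseline correction** per subject and channel: each subject's grand
   mean across their retained epochs is subtracted.
7. **Band decomposition** into delta (0.5–4 Hz), theta (4–8), alpha (8–13),
   beta (13–30), gamma (30–40), with the unfiltered broad band kept
   alongside; the ECG channel is attached bit-identically to every band.

**Filter design choices.** All filters are applied forward–backward
(zero phase) so the bands stay time-aligned; for the Bessel filter this
deliberately sacrifices its maximally-flat group delay in exchange for zero
phase. FIR transition bandwidths follow `min(max(0.25·f, 2 Hz), headroom)`
per edge; at a 0.5 Hz lower edge this yields a ≈1700-tap kernel. A literal
25%-of-cutoff transition at 0.5 Hz would require ≈6800 taps — longer than a
2560-sample epoch — and is therefore not usable for per-epoch filtering;
the 2 Hz floor is the standard practical compromise. The Bessel filter is
designed from the analog prototype (reverse Bessel polynomial roots,
−3 dB normalization) via lowpass→bandpass transform and bilinear transform,
and is applied as a cascade of second-order sections: with a 0.25 Hz edge at
256 Hz the pooled transfer-function polynomial is numerically unusable.
One consequence worth knowing: the Bessel magnitude is Gaussian-like, so a
60 Hz tone is attenuated by ≈19 dB after zero-phase application — more
stop-band attenuation at 1.5× the upper edge is not achievable with this
filter family at any order.

Zero-phase FIR filtering is implemented in the frequency domain
(response |H|²) on odd-reflection-padded signals; the band decomposition
batches all five bands over one shared forward FFT (compiled code), which
is what makes per-epoch filtering of whole cohorts affordable.

## Entropy estimators

All six estimators are computed per channel per epoch (21 values per band
per epoch). N = 2560 throughout.

- **Approximate entropy** `ApEn(m, r)`: Φ^m − Φ^(m+1), where Φ^m is the
  mean natural log of the fraction of length-m templates within Chebyshev
  distance r; self-matches included. Template counting is compiled
  (O(N²) pairwise sweep).
- **Sample entropy** `SampEn(m, r)`: −ln(A/B) with B and A the m- and
  (m+1)-template match probabilities, self-matches excluded, both template
  sets of size N − m. If no templates match, the statistic is undefined:
  the estimator returns `NaN` and the feature assembly drops that epoch
  with a warning, rather than inventing a cap. A zero-variance series
  (possible only if the flat-epoch rejector is bypassed) returns 0 with a
  warning, as a flat channel carries no irregularity.
- **Spectral entropy**: Shannon entropy of the Welch PSD normalized to a
  probability vector, divided by ln Ω (Ω = number of PSD bins); in [0, 1].
  Welch defaults: 1-s Hamming segments, 50% overlap — standard EEG
  practice; all bins up to the Nyquist frequency are retained.
- **SVD entropy**: Shannon entropy (base 2, normalized by log₂ L) of the
  normalized squared singular values of the delay-embedding
  (Hankel-structured) matrix. The embedding dimensions are not pinned down
  by the method's usual presentation, which also mixes log bases between
  the normalization and the summand; this implementation uses one
  consistent base (2) so the maximum is exactly 1, and defaults to
  embedding dimension 10 with delay 2, both configurable.
- **Rényi entropy** (order α = 2, base-2 log) of the amplitude
  distribution, estimated by an equal-width histogram over the epoch's
  observed range with 100 bins by default. The histogram rule is the main
  replication degree of freedom for this estimator and the bin count is
  exposed as a sensitivity parameter.
- **Wavelet entropy**: Shannon entropy (natural log) of the relative
  Morlet-wavelet energies across J = 10 log-spaced scales covering
  0.5–40 Hz; the averaging window defaults to the whole epoch, giving one
  value per channel per epoch. A shorter window yields the mean over
  successive windows.

For the template entropies, r = r_sd × SD with the SD computed per epoch
per channel (the per-epoch reading of an ambiguous convention; it makes the
features scale-invariant per epoch). The defaults m = 2, r_sd = 0.2 (ApEn)
and m = 1, r_sd = 0.15 (SampEn) correspond to the grid-search selections
reported for this protocol, and the grid search itself
(`select_apen_sampen_params()`) re-derives them on any cohort: grid
m ∈ {1,2} × r_sd ∈ {0.1, 0.15, 0.2, 0.25}, ten subjects per class, RBF-SVM
with 5-fold CV, highest mean balanced accuracy wins; ties resolve to the
smaller m, then smaller r_sd (the cheaper, lower-variance estimator). The
whole grid costs a single O(N²) sweep per series (all eight cells are
counted in one pass). Whether the original protocol fed the search
broad-band features only or averaged across bands is ambiguous;
band-averaging is the default here, with `band_mode = "broad"` available.

## Classification protocol

Epoch-wise stratified 10-fold cross-validation; per training fold:
z-scoring (training statistics only — scaling is not part of the described
protocol but RBF-SVM, kNN and PCA are scale-sensitive; it can be toggled
off), SMOTE oversampling of the minority class (synthetic points are convex
combinations of a minority sample and one of its 5 nearest minority
neighbours), then PCA keeping the smallest component count reaching 95%
explained variance. The test fold is projected with training-fold
statistics and loadings only; the suite contains an explicit leakage test.

Classifiers: RBF-SVM with γ = 1/(n_features × variance of the processed
training matrix); kNN with k selected per fold by an inner 10-fold
balanced-accuracy search over {2,…,10, 12, 15, 20} (Euclidean distance,
deterministic nearest-neighbour tie-break); random forest (100 trees);
gradient boosting (100 rounds, learning rate 0.1, depth 3, backed by
xgboost). PNES is the positive class; precision, recall, and balanced
accuracy are computed per fold and averaged unweighted, with
zero-denominator folds flagged and excluded.

Epoch-wise folds replicate the reference protocol and share subjects
between training and test folds — a known optimism source, acknowledged as
such; `subject_wise = TRUE` provides grouped folds as the methodologically
safer alternative.

## Band importance and exclusion

Grouped permutation importance of a band: reference balanced accuracy s on
the validation fold, minus the mean score over K = 10 corruptions in which
all 21 of the band's feature columns are row-shuffled (each column
independently by default — the stronger corruption — or with one shared
permutation; both modes are available and recorded). Importances are
averaged over the CV folds. An exhaustive mode enumerates all n!
permutations on tiny validation sets, used by the tests to pin the
Monte-Carlo estimator to the exact mean. The band-exclusion experiment
drops one band at a time and re-runs the full CV on the remainder,
reporting the no-exclusion row alongside; the ECG features of the remaining
bands stay in every configuration, and the importance column comes from the
all-bands model.

## The synthetic cohort

`generate_cohort()` produces a labelled stand-in cohort. Per subject, each
EEG channel is a sum of 1/f^β background noise (β = 1.1), a band-limited
oscillation in each configured informative band (theta by default, centre
6 Hz, baseline amplitude 12 µV against 10 µV noise SD), a mild always-on
10 Hz alpha component, and a shared source mixed across channels with
fixed montage weights to create realistic cross-channel correlation. The
ECG leads carry a Gaussian-bump QRS/T beat train whose RR intervals jitter
with class-dependent SD (50 vs 20 ms at full contrast). The class contrast
enters as an oscillation amplitude ratio (2.5 at `contrast = 1`, split
symmetrically between the classes), optionally a spectral-exponent
difference (0 by default, so the contrast stays confined to the informative
bands), and the RR-jitter difference. `contrast = 0` makes the classes
statistically identical.

Two generator properties are load-bearing for the tests. First, epochs are
*exchangeable across subjects* at zero contrast: oscillation phase and
amplitude modulation are re-drawn every epoch-length segment, and the
shared-source mixing weights are fixed rather than per-subject random. Any
persistent per-subject signature would let epoch-wise cross-validation
memorize subject identity and push the null cohort's accuracy above
chance — a leakage artifact, not a classifier property. Second, the
contrast magnitudes are calibration choices, not claims about PNES
physiology: nothing in the underlying study describes the distribution of
its recordings beyond band definitions, so the defaults were chosen once to
make the planted effect comparable to a strong clinical effect, and are
configuration.

What the generator deliberately does **not** emulate: seizure morphology,
forward head models, eye-blink/EMG artifacts (beyond the simple amplitude
outliers used to exercise the rejector), age/sex structure, and
inter-subject anatomical variability. Passing tests on this cohort
demonstrate that the pipeline recovers planted, entropy-visible class
structure under the stated protocol — not that the same accuracy would be
obtained on clinical recordings.

## Recovery experiments and their design

The end-to-end checks use a cohort of 10 subjects per class with 20 epochs
each (400 epochs — large enough for stable 10-fold metrics, small enough
for a desk-scale run; the full-size 48/29 default exercises the SMOTE path
but is not needed for the properties under test). Rényi features with kNN
reach high balanced accuracy at full contrast and sit within 3 standard
errors of 0.5 at zero contrast.

Band recovery (importance ranking and exclusion drop) is evaluated over the
five *disjoint* narrow bands, excluding broad. The broad band contains the
theta range, so with broad present the planted signal is duplicated:
excluding theta then costs nothing and the recovery question is ill-posed.
This mirrors the empirical observation in the reference protocol that
excluding the broad band left accuracy essentially unchanged. Neighbouring
bands still pick up a small share of the contrast through filter transition
bands (delta's upper transition reaches a 6 Hz oscillation), which the
tests accommodate with margins rather than near-zero requirements.

## Degenerate inputs and numerical conventions

- Zero-variance series: ApEn/SampEn return 0 with a warning; SVD and
  spectral entropy raise errors on all-zero input.
- Undefined SampEn (no matches): `NaN`, epoch dropped at feature assembly.
- Histogram top edge: the maximum lands in the last bin.
- kNN ties: resolved toward the class of the single nearest neighbour, so
  the whole pipeline is bit-reproducible under a fixed seed (a randomized
  tie-break would break the byte-identical determinism contract of
  `run_experiment()`).
- EDF I/O quantizes to 16 bits against each channel's observed physical
  range; round-trip error is bounded by one quantization step.

## Known limitations

- The synthetic cohort is a structural stand-in; headline accuracies on it
  are not comparable to accuracies on clinical data.
- Epoch-wise CV (the default, for fidelity to the protocol) shares
  subjects across folds; use `subject_wise = TRUE` for deployable
  estimates.
- The amplitude-criterion artifact rejector approximates, but does not
  reproduce, consensus-threshold rejection.
- The Rényi histogram rule and the SVD embedding dimensions are exposed
  parameters precisely because the reference protocol does not determine
  them; conclusions that depend sensitively on either should be probed
  through those parameters.
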