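# Synthetic cohort generator.
#
# The clinical recordings behind this analysis cannot be redistributed, so the
# pipeline is exercised on a synthetic stand-in cohort whose two classes differ
# in exactly the properties entropy estimators are sensitive to: band-limited
# oscillation amplitude (confined to configurable "informative" bands),
# optionally the spectral exponent of the 1/f background, and the beat-to-beat
# regularity of a synthetic ECG.  None of the defaults is a claim about PNES
# physiology; they are calibration choices documented in the methods vignette.

#' Configuration for a synthetic EEG/ECG cohort
#'
#' @param n_per_class named integer vector: subjects per class
#'   (default `c(PNES = 48, epilepsy = 29)`, mirroring the study imbalance).
#' @param epochs_per_subject number of 10-s epochs of signal generated per
#'   subject (plus one, so that a trailing partial epoch never truncates data).
#' @param fs sampling rate in Hz; must exceed twice the highest analysis
#'   frequency (40 Hz).
#' @param epoch_len epoch length in seconds.
#' @param channels ordered channel names; must contain `"ECG+"` and `"ECG-"`.
#' @param informative_bands bands carrying the class contrast (subset of
#'   delta/theta/alpha/beta/gamma).
#' @param contrast scalar scaling of every class difference; 0 makes the two
#'   classes statistically identical, 1 is the default "strong" contrast.
#' @param osc_amp_ratio oscillation amplitude ratio between the classes in an
#'   informative band, at `contrast = 1`.
#' @param osc_amp_uV baseline oscillation amplitude (micro-volts).
#' @param noise_sd_uV standard deviation of the 1/f background (micro-volts).
#' @param spectral_exponent baseline exponent beta of the 1/f^beta background.
#' @param spectral_exponent_diff class difference in the spectral exponent at
#'   `contrast = 1` (default 0: the contrast stays in `informative_bands`).
#' @param shared_source_sd_uV amplitude of a common source mixed into every
#'   EEG channel (creates cross-channel correlation).
#' @param subject_sd log-normal sd of per-subject amplitude variability.
#' @param hrv_params list with `mean_rr` (s) and `rr_jitter` (s), each a named
#'   vector with one entry per class at `contrast = 1`; jitter differences are
#'   scaled by `contrast` around their midpoint.
#' @param seed integer master seed.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_per_class = c(PNES = 48, epilepsy = 29),
                          epochs_per_subject = 20,
                          fs = 256,
                          epoch_len = 10,
                          channels = common_channels(),
                          informative_bands = "theta",
                          contrast = 1,
                          osc_amp_ratio = 2.5,
                          osc_amp_uV = 12,
                          noise_sd_uV = 10,
                          spectral_exponent = 1.1,
                          spectral_exponent_diff = 0,
                          shared_source_sd_uV = 4,
                          subject_sd = 0.05,
                          hrv_params = list(
                            mean_rr = c(PNES = 0.85, epilepsy = 0.85),
                            rr_jitter = c(PNES = 0.05, epilepsy = 0.02)),
                          seed = 1L) {
  if (length(n_per_class) != 2 || any(n_per_class < 1) ||
      any(n_per_class != round(n_per_class)))
    stop("n_per_class must be two positive integers")
  if (is.null(names(n_per_class))) names(n_per_class) <- c("PNES", "epilepsy")
  if (fs <= 2 * 40)
    stop("fs must exceed twice the highest analysis frequency (40 Hz)")
  if (epochs_per_subject < 1) stop("epochs_per_subject must be positive")
  if (!all(c("ECG+", "ECG-") %in% channels))
    stop("channel list must contain ECG+ and ECG-")
  bad <- setdiff(informative_bands, narrow_band_names())
  if (length(bad)) stop("unknown informative band(s): ",
                        paste(bad, collapse = ", "))
  structure(list(
    n_per_class = n_per_class, epochs_per_subject = epochs_per_subject,
    fs = fs, epoch_len = epoch_len, channels = channels,
    informative_bands = informative_bands, contrast = contrast,
    osc_amp_ratio = osc_amp_ratio, osc_amp_uV = osc_amp_uV,
    noise_sd_uV = noise_sd_uV, spectral_exponent = spectral_exponent,
    spectral_exponent_diff = spectral_exponent_diff,
    shared_source_sd_uV = shared_source_sd_uV, subject_sd = subject_sd,
    hrv_params = hrv_params, seed = as.integer(seed)
  ), class = "cohort_config")
}

# Gaussian 1/f^(beta) noise of length n, unit variance, via spectral
# shaping of complex white noise (single inverse FFT).
colored_noise <- function(n, beta) {
  nf <- stats::nextn(n, 2)
  nfreq <- nf / 2
  amp <- c(0, (1:nfreq)^(-beta / 2),
           if (nfreq > 1) ((nfreq - 1):1)^(-beta / 2))
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf))
  x <- Re(stats::fft(z * amp, inverse = TRUE))[1:n]
  (x - mean(x)) / stats::sd(x)
}

# Band oscillation: sinusoid at the band's centre frequency with slow random
# amplitude modulation.  Phase and AM are re-drawn for every epoch-length
# segment so that epochs carry no persistent per-subject signature (at zero
# class contrast, epochs must be exchangeable across subjects, otherwise
# epoch-wise cross-validation could learn subject identity).
band_oscillation <- function(n, fs, freq, amp, seg_len = 10 * fs) {
  out <- numeric(n)
  for (st in seq(1, n, by = seg_len)) {
    en <- min(st + seg_len - 1, n)
    t <- (0:(en - st)) / fs
    am <- 1 + 0.3 * sin(2 * pi * stats::runif(1, 0.05, 0.15) * t +
                          stats::runif(1, 0, 2 * pi))
    out[st:en] <- am * sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi))
  }
  amp * out
}

band_centre_freq <- function(band) {
  c(delta = 2, theta = 6, alpha = 10, beta = 20, gamma = 35)[[band]]
}

#' Generate a synthetic single-lead ECG
#'
#' Quasi-periodic beat train: Gaussian-bump QRS complex plus a smaller T wave,
#' with per-beat RR intervals drawn as `mean_rr` plus Gaussian jitter.
#'
#' @param duration signal length in seconds (must fit at least one beat).
#' @param fs sampling rate (Hz).
#' @param mean_rr mean RR interval (s), positive.
#' @param rr_jitter standard deviation of the RR interval (s), non-negative.
#' @param seed optional integer seed.
#' @return Numeric vector of `duration * fs` samples (arbitrary mV-scale units).
#' @export
generate_synthetic_ecg <- function(duration, fs, mean_rr = 0.85,
                                   rr_jitter = 0.02, seed = NULL) {
  if (mean_rr <= 0) stop("mean_rr must be positive")
  if (rr_jitter < 0) stop("rr_jitter must be non-negative")
  if (duration < mean_rr) stop("duration shorter than one beat")
  gen <- function() {
    n <- round(duration * fs)
    t <- (0:(n - 1)) / fs
    beats <- numeric(0)
    tk <- mean_rr / 2
    while (tk < duration) {
      beats <- c(beats, tk)
      step <- mean_rr + if (rr_jitter > 0) stats::rnorm(1, 0, rr_jitter) else 0
      tk <- tk + max(step, 0.3)
    }
    x <- numeric(n)
    for (b in beats) {
      # each beat only influences a +-0.6 s window around its R peak
      lo <- max(1L, floor((b - 0.6) * fs)); hi <- min(n, ceiling((b + 0.6) * fs))
      tw <- t[lo:hi]
      x[lo:hi] <- x[lo:hi] + exp(-(tw - b)^2 / (2 * 0.012^2)) -
        0.15 * exp(-(tw - b - 0.05)^2 / (2 * 0.02^2)) +
        0.25 * exp(-(tw - b - 0.25)^2 / (2 * 0.04^2))
    }
    x
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# One subject's raw multichannel recording (EEG in uV, ECG leads in mV-scale
# arbitrary units).
generate_recording <- function(config, subject_id, class_label, seed) {
  with_seed(seed, {
    fs <- config$fs
    n <- round((config$epochs_per_subject + 1) * config$epoch_len * fs)
    sgn <- if (class_label == names(config$n_per_class)[1]) 1 else -1
    ctr <- config$contrast
    beta <- config$spectral_exponent +
      sgn * ctr * config$spectral_exponent_diff / 2
    subj_gain <- exp(stats::rnorm(1, 0, config$subject_sd))
    shared <- colored_noise(n, 1) * config$shared_source_sd_uV
    eeg_names <- setdiff(config$channels, c("ECG+", "ECG-"))
    sig <- matrix(0, length(config$channels), n,
                  dimnames = list(config$channels, NULL))
    # fixed montage mixing of the shared source: subjects must not carry an
    # identifying spatial fingerprint, or epoch-wise CV could learn subject
    # identity instead of class
    mix <- 0.5 + 0.5 * (seq_along(eeg_names) - 1) / (length(eeg_names) - 1)
    # oscillation amplitude per class: ratio^(+-contrast/2) around baseline
    for (ci in seq_along(eeg_names)) {
      x <- colored_noise(n, beta) * config$noise_sd_uV
      seg <- round(config$epoch_len * fs)
      for (band in config$informative_bands) {
        amp <- config$osc_amp_uV * config$osc_amp_ratio^(sgn * ctr / 2)
        x <- x + band_oscillation(n, fs, band_centre_freq(band), amp, seg)
      }
      # mild always-on alpha so spectra look EEG-like in both classes
      if (!"alpha" %in% config$informative_bands)
        x <- x + band_oscillation(n, fs, 10, 0.4 * config$osc_amp_uV, seg)
      sig[eeg_names[ci], ] <- x + shared * mix[ci]
    }
    hp <- config$hrv_params
    mid_j <- mean(hp$rr_jitter)
    jitter <- max(mid_j + ctr * (hp$rr_jitter[[class_label]] - mid_j), 0)
    ecg <- generate_synthetic_ecg(n / fs, fs,
                                  mean_rr = hp$mean_rr[[class_label]],
                                  rr_jitter = jitter)
    noise_ecg <- function() stats::rnorm(n, 0, 0.01)
    sig["ECG+", ] <- 0.6 * ecg + noise_ecg()
    sig["ECG-", ] <- -0.4 * ecg + noise_ecg()
    sig[eeg_names, ] <- sig[eeg_names, , drop = FALSE] * subj_gain
    new_recording(sig, fs, subject_id, class_label)
  })
}

new_recording <- function(signal, fs, subject_id, class_label) {
  stopifnot(is.matrix(signal), !is.null(rownames(signal)))
  if (any(!is.finite(signal))) stop("recording contains non-finite samples")
  structure(list(signal = signal, fs = fs, channels = rownames(signal),
                 subject_id = subject_id, class_label = class_label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$class_label %||% "?", nrow(x$signal),
              ncol(x$signal), x$fs))
  invisible(x)
}

#' Generate a labelled synthetic cohort
#'
#' Deterministic given `config$seed`: each subject is generated under its own
#' derived seed, so the cohort is reproducible at subject level as well.
#'
#' @param config a [cohort_config()].
#' @return List of recordings (class `eeg_recording`), one per subject, with
#'   `subject_id`, `class_label`, `fs`, `channels`, and a channels-by-samples
#'   `signal` matrix.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  classes <- rep(names(config$n_per_class), config$n_per_class)
  n <- length(classes)
  seeds <- derive_seeds(config$seed, n)
  lapply(seq_len(n), function(i) {
    generate_recording(config, sprintf("S%03d", i), classes[i], seeds[i])
  })
}

#' Write cohort class labels as a sidecar TSV
#'
#' @param recordings list of recordings.
#' @param path output file.
#' @export
write_labels_tsv <- function(recordings, path) {
  df <- data.frame(
    subject_id = vapply(recordings, `[[`, "", "subject_id"),
    class_label = vapply(recordings, `[[`, "", "class_label"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
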