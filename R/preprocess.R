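# Signal-conditioning chain: resample -> broad FIR bandpass (EEG) -> ECG
# derivation and Bessel filtering -> 10-s epoching -> amplitude-based
# artifact rejection -> per-subject baseline correction -> band
# decomposition.  All filters are applied zero-phase (forward-backward) so
# bands stay time-aligned; see the methods vignette for the design choices.

#' Resample a recording to 256 Hz and select the common montage
#'
#' Recordings at 512 or 1024 Hz are decimated after zero-phase FIR
#' anti-alias filtering; 256 Hz input passes through unchanged apart from
#' channel selection.
#'
#' @param recording an `eeg_recording` at 256, 512, or 1024 Hz.
#' @param channels the common electrode list to retain.
#' @return The recording at 256 Hz with channels in montage order.
#' @export
resample_to_256 <- function(recording, channels = common_channels()) {
  fs <- recording$fs
  if (!fs %in% c(256, 512, 1024))
    stop("unsupported sampling rate: ", fs, " (expected 256, 512, or 1024)")
  missing <- setdiff(channels, recording$channels)
  if (length(missing))
    stop("missing common electrode(s): ", paste(missing, collapse = ", "))
  sig <- recording$signal[channels, , drop = FALSE]
  if (fs > 256) {
    k <- fs / 256
    h <- fir_lowpass(0.8 * 128, fs, trans = 0.2 * 128)
    filt <- fft_filtfilt(t(sig), h)
    sig <- t(filt[seq(1, nrow(filt), by = k), , drop = FALSE])
    rownames(sig) <- channels
  }
  new_recording(sig, 256, recording$subject_id, recording$class_label)
}

#' Broad-band FIR filtering of the EEG channels
#'
#' Zero-phase Hamming-window FIR bandpass (default 0.5--40 Hz) applied to
#' the EEG channels of a continuous recording; the ECG leads are left
#' untouched (they get their own Bessel chain).
#'
#' @param recording an `eeg_recording` at 256 Hz.
#' @param low,high cutoff frequencies in Hz.
#' @return The filtered recording.
#' @export
bandpass_eeg <- function(recording, low = 0.5, high = 40) {
  fs <- recording$fs
  if (low <= 0 || high >= fs / 2 || low >= high)
    stop("cutoffs must lie inside (0, fs/2)")
  eeg <- intersect(recording$channels, eeg_channel_names())
  h <- fir_bandpass(low, high, fs)
  sig <- recording$signal
  sig[eeg, ] <- t(fft_filtfilt(t(sig[eeg, , drop = FALSE]), h))
  new_recording(sig, fs, recording$subject_id, recording$class_label)
}

#' Derive and filter the single ECG channel
#'
#' The ECG channel is (ECG+) - (ECG-), Bessel IIR band-passed 0.25--40 Hz
#' (zero-phase), then high-passed at 0.05 Hz to remove baseline wander.
#' The same derived ECG accompanies every EEG frequency band downstream.
#'
#' @param recording an `eeg_recording` containing `ECG+` and `ECG-` leads.
#' @param order Bessel bandpass order.
#' @return Numeric vector: the derived, filtered ECG.
#' @export
derive_and_filter_ecg <- function(recording, order = 4) {
  for (lead in c("ECG+", "ECG-"))
    if (!lead %in% recording$channels) stop("missing ECG lead: ", lead)
  raw <- recording$signal["ECG+", ] - recording$signal["ECG-", ]
  fs <- recording$fs
  bp <- bessel_filter(order, c(0.25, 40), fs, "pass")
  hp <- bessel_filter(2, 0.05, fs, "high")
  iir_filtfilt(iir_filtfilt(raw, bp), hp)
}

new_epoch_set <- function(data, subject_ids, class_labels, fs, band,
                          channels) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(subject_ids),
            dim(data)[2] == length(channels))
  structure(list(data = data, subject_ids = subject_ids,
                 class_labels = class_labels, fs = fs, band = band,
                 channels = channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> band=%s: %d epochs x %d channels x %d samples\n",
              x$band, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3]))
  invisible(x)
}

n_epochs <- function(es) dim(es$data)[1]

#' Segment a recording into non-overlapping epochs
#'
#' The EEG channels are combined with the derived ECG channel (passed in as
#' `ecg`), giving 21 channels per epoch.  Trailing samples that do not fill
#' a complete epoch are dropped.
#'
#' @param recording an `eeg_recording` (EEG already broad-band filtered).
#' @param ecg derived ECG vector from [derive_and_filter_ecg()]; if `NULL`
#'   it is computed here.
#' @param epoch_len epoch length in seconds.
#' @return An `epoch_set` with band `"broad"`.
#' @export
epoch_signal <- function(recording, ecg = NULL, epoch_len = 10) {
  fs <- recording$fs
  len <- round(epoch_len * fs)
  n <- ncol(recording$signal)
  if (n < len) stop("recording shorter than one epoch")
  if (is.null(ecg)) ecg <- derive_and_filter_ecg(recording)
  n_ep <- floor(n / len)
  eeg <- intersect(recording$channels, eeg_channel_names())
  chans <- c(eeg, "ECG")
  data <- array(0, c(n_ep, length(chans), len),
                dimnames = list(NULL, chans, NULL))
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1) * len + 1):(e * len)
    data[e, eeg, ] <- recording$signal[eeg, idx]
    data[e, "ECG", ] <- ecg[idx]
  }
  new_epoch_set(data, rep(recording$subject_id, n_ep),
                rep(recording$class_label, n_ep), fs, "broad", chans)
}

# Concatenate epoch sets (same band/fs/channels).
bind_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  data <- do.call(abind3, lapply(sets, `[[`, "data"))
  new_epoch_set(data,
                unlist(lapply(sets, `[[`, "subject_ids")),
                unlist(lapply(sets, `[[`, "class_labels")),
                sets[[1]]$fs, sets[[1]]$band, sets[[1]]$channels)
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], 0)), d[2], d[3]),
               dimnames = list(NULL, dimnames(parts[[1]])[[2]], NULL))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

subset_epochs <- function(es, keep) {
  new_epoch_set(es$data[keep, , , drop = FALSE], es$subject_ids[keep],
                es$class_labels[keep], es$fs, es$band, es$channels)
}

#' Reject flat and noisy epochs
#'
#' Removes (a) flat epochs, where every EEG channel's peak-to-peak
#' amplitude stays below `flat_uV`; (b) noisy epochs, where any EEG
#' channel's peak-to-peak amplitude exceeds `ptp_uV` (an amplitude-criterion
#' stand-in for consensus-threshold rejection); and (c) epochs whose ECG
#' peak-to-peak falls below `ecg_floor` (stand-in for visual flat-ECG
#' screening).
#'
#' @param epochs an `epoch_set` (EEG in micro-volts).
#' @param flat_uV flatness threshold (peak-to-peak, micro-volts).
#' @param ptp_uV noise threshold (peak-to-peak, micro-volts).
#' @param ecg_floor minimum ECG peak-to-peak amplitude.
#' @return List with `epochs` (survivors) and `log` (data frame of rejected
#'   epoch indices and reasons).
#' @export
reject_artifacts <- function(epochs, flat_uV = 1, ptp_uV = 300,
                             ecg_floor = 0.05) {
  if (flat_uV <= 0 || ptp_uV <= 0 || ecg_floor <= 0)
    stop("rejection thresholds must be positive")
  eeg <- setdiff(epochs$channels, "ECG")
  E <- n_epochs(epochs)
  ptp <- function(v) diff(range(v))
  reasons <- character(0); idx <- integer(0)
  keep <- rep(TRUE, E)
  for (e in seq_len(E)) {
    eeg_ptp <- apply(epochs$data[e, eeg, , drop = FALSE], 2, ptp)
    ecg_ptp <- ptp(epochs$data[e, "ECG", ])
    reason <- if (all(eeg_ptp < flat_uV)) "flat"
      else if (any(eeg_ptp > ptp_uV)) "noisy"
      else if (ecg_ptp < ecg_floor) "flat_ecg"
      else NA_character_
    if (!is.na(reason)) {
      keep[e] <- FALSE
      idx <- c(idx, e); reasons <- c(reasons, reason)
    }
  }
  list(epochs = subset_epochs(epochs, keep),
       log = data.frame(epoch = idx, reason = reasons,
                        subject = epochs$subject_ids[idx]))
}

#' Per-subject baseline correction
#'
#' For each subject and channel, subtracts that subject's grand mean
#' (computed across all retained epochs) from every sample.
#'
#' @param epochs an `epoch_set` carrying subject ids.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  subj <- factor(epochs$subject_ids)
  cnt <- as.vector(table(subj)) * dim(epochs$data)[3]
  for (ch in seq_along(epochs$channels)) {
    M <- epochs$data[, ch, , drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, nrow = 1)
    mu <- rowsum(rowSums(M), subj)[, 1] / cnt
    epochs$data[, ch, ] <- M - mu[as.integer(subj)]
  }
  epochs
}

#' Decompose epochs into frequency bands
#'
#' EEG channels are band-pass filtered (zero-phase FIR) into delta, theta,
#' alpha, beta, and gamma; `broad` is the unmodified input.  The derived ECG
#' channel is attached bit-identically to every band's epoch set.
#'
#' @param epochs a broad-band, baseline-corrected `epoch_set`.
#' @param bands band names to produce (default all six).
#' @return Named list of `epoch_set`s, one per band.
#' @export
decompose_bands <- function(epochs, bands = eeg_bands()$name) {
  defs <- eeg_bands(bands)
  eeg_ix <- which(epochs$channels != "ECG")
  narrow <- defs[defs$name != "broad", , drop = FALSE]
  filtered <- list()
  if (nrow(narrow)) {
    kernels <- lapply(seq_len(nrow(narrow)), function(b)
      fir_bandpass(narrow$low[b], narrow$high[b], epochs$fs))
    res <- decompose_bands_cpp(epochs$data, eeg_ix, kernels)
    for (b in seq_len(nrow(narrow))) {
      dimnames(res[[b]]) <- dimnames(epochs$data)
      filtered[[narrow$name[b]]] <- res[[b]]
    }
  }
  out <- list()
  for (b in seq_len(nrow(defs))) {
    band <- defs$name[b]
    es <- epochs
    es$band <- band
    if (band != "broad") es$data <- filtered[[band]]
    out[[band]] <- es
  }
  out
}

#' Run the full preprocessing chain on a cohort
#'
#' Resampling, broad-band EEG filtering, ECG derivation, epoching, artifact
#' rejection, per-subject baseline correction, and band decomposition.
#'
#' @param recordings list of `eeg_recording`s.
#' @param epoch_len epoch length (s).
#' @param bands bands to produce.
#' @param flat_uV,ptp_uV,ecg_floor rejection thresholds, see
#'   [reject_artifacts()].
#' @return List with `bands` (named list of `epoch_set`s) and `rejection_log`.
#' @export
preprocess_cohort <- function(recordings, epoch_len = 10,
                              bands = eeg_bands()$name,
                              flat_uV = 1, ptp_uV = 300, ecg_floor = 0.05) {
  sets <- list(); logs <- list()
  for (rec in recordings) {
    rec <- resample_to_256(rec)
    rec_f <- bandpass_eeg(rec)
    ecg <- derive_and_filter_ecg(rec)
    ep <- epoch_signal(rec_f, ecg, epoch_len)
    rej <- reject_artifacts(ep, flat_uV, ptp_uV, ecg_floor)
    sets[[length(sets) + 1]] <- rej$epochs
    logs[[length(logs) + 1]] <- rej$log
  }
  all_ep <- bind_epoch_sets(sets)
  all_ep <- baseline_correct(all_ep)
  list(bands = decompose_bands(all_ep, bands),
       rejection_log = do.call(rbind, logs))
}
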