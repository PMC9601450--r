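fs <- 256

# a minimal two-channel-plus-ECG recording from explicit signals
toy_recording <- function(signals, fs = 256, id = "t1", label = "PNES") {
  sig <- do.call(rbind, signals)
  rownames(sig) <- names(signals)
  pnesentropy:::new_recording(sig, fs, id, label)
}

test_that("resampling passes 256 Hz through and halves 512 Hz", {
  coh <- generate_cohort(tiny_cohort_config(seed = 1))
  rec <- coh[[1]]
  out <- resample_to_256(rec)
  expect_identical(out$signal, rec$signal[common_channels(), ])

  # synthetic 512 Hz recording: 10 s, pure 10 Hz tone on every channel
  t512 <- seq(0, 10 - 1 / 512, by = 1 / 512)
  sig <- matrix(rep(sin(2 * pi * 10 * t512), 22), nrow = 22, byrow = TRUE)
  rownames(sig) <- common_channels()
  rec512 <- pnesentropy:::new_recording(sig, 512, "x", "PNES")
  out <- resample_to_256(rec512)
  expect_identical(out$fs, 256)
  expect_identical(ncol(out$signal), 2560L)
  # dominant DFT bin still 10 Hz, amplitude within 1%
  X <- Mod(fft(out$signal[1, ]))[1:1280]
  expect_equal(which.max(X[-1]), 100L)  # 10 Hz at 0.1 Hz resolution
  amp <- 2 * max(X[-1]) / 2560
  expect_lt(abs(amp - 1), 0.01)

  expect_error(resample_to_256(
    pnesentropy:::new_recording(sig, 500, "x", "PNES")), "unsupported")
  rec_missing <- pnesentropy:::new_recording(sig[-1, ], 512, "x", "PNES")
  expect_error(resample_to_256(rec_missing), "Fp1")
})

test_that("broad-band FIR meets its pass- and stop-band contracts", {
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  chans <- common_channels()
  mk <- function(x) {
    sig <- matrix(rep(x, 22), nrow = 22, byrow = TRUE)
    rownames(sig) <- chans
    pnesentropy:::new_recording(sig, fs, "x", "PNES")
  }
  out50 <- bandpass_eeg(mk(sin(2 * pi * 50 * t)))
  expect_lt(20 * log10(sd(out50$signal["Cz", ]) / sd(sin(2 * pi * 50 * t))),
            -20)
  out10 <- bandpass_eeg(mk(sin(2 * pi * 10 * t)))
  expect_lt(abs(sd(out10$signal["Cz", ]) / sd(sin(2 * pi * 10 * t)) - 1),
            0.05)
  # ECG leads untouched by the EEG filter
  expect_identical(out10$signal["ECG+", ], mk(sin(2 * pi * 10 * t))$signal["ECG+", ])

  # white noise: out-of-band power fraction < 1%
  set.seed(2)
  outwn <- bandpass_eeg(mk(rnorm(length(t))))
  ps <- welch_psd(outwn$signal["Cz", ], fs, seg_sec = 2)
  oob <- ps$freq < 0.25 | ps$freq > 45
  expect_lt(sum(ps$psd[oob]) / sum(ps$psd), 0.01)

  expect_error(bandpass_eeg(mk(t), low = 0, high = 40), "cutoffs")
})

test_that("pass-band filtering is near-idempotent", {
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  sig <- matrix(rep(sin(2 * pi * 10 * t), 22), nrow = 22, byrow = TRUE)
  rownames(sig) <- common_channels()
  rec <- pnesentropy:::new_recording(sig, fs, "x", "PNES")
  once <- bandpass_eeg(rec)
  twice <- bandpass_eeg(once)
  expect_lt(abs(sd(twice$signal["Cz", ]) / sd(once$signal["Cz", ]) - 1),
            0.05)
})

test_that("ECG derivation subtracts leads and removes drift", {
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  base <- generate_synthetic_ecg(120, fs, 0.8, 0.02, seed = 3)
  blank <- matrix(0, 20, length(t))
  rownames(blank) <- pnesentropy:::eeg_channel_names()

  # identical leads cancel to ~0
  rec <- toy_recording(c(
    stats::setNames(lapply(seq_len(20), function(i) blank[i, ]),
                    rownames(blank)),
    list(`ECG+` = base, `ECG-` = base)))
  expect_lt(max(abs(derive_and_filter_ecg(rec))), 1e-8)

  # 0.02 Hz drift 5x the QRS amplitude: power at the drift frequency
  # attenuated by >= 90%
  drift <- 5 * sin(2 * pi * 0.02 * t)
  rec2 <- toy_recording(c(
    stats::setNames(lapply(seq_len(20), function(i) blank[i, ]),
                    rownames(blank)),
    list(`ECG+` = base + drift, `ECG-` = -base * 0)))
  out <- derive_and_filter_ecg(rec2)
  p_at <- function(x, f) {
    ps <- welch_psd(x, fs, seg_sec = 64)
    ps$psd[which.min(abs(ps$freq - f))]
  }
  expect_lt(p_at(out, 0.02) / p_at(base + drift, 0.02), 0.1)

  # 60 Hz tone strongly attenuated (Bessel stop band)
  rec3 <- toy_recording(c(
    stats::setNames(lapply(seq_len(20), function(i) blank[i, ]),
                    rownames(blank)),
    list(`ECG+` = sin(2 * pi * 60 * t), `ECG-` = 0 * t)))
  out3 <- derive_and_filter_ecg(rec3)
  mid <- seq(20 * fs, 100 * fs)
  expect_lt(20 * log10(sd(out3[mid]) / sd(sin(2 * pi * 60 * t)[mid])), -18)

  rec4 <- rec
  rec4$signal <- rec4$signal[setdiff(rec4$channels, "ECG-"), ]
  rec4$channels <- rownames(rec4$signal)
  expect_error(derive_and_filter_ecg(rec4), "ECG-")
})

test_that("epoching floors to whole epochs and preserves samples", {
  n95 <- 95 * fs
  sig <- matrix(rnorm(22 * n95), nrow = 22)
  rownames(sig) <- common_channels()
  rec <- pnesentropy:::new_recording(sig, fs, "s9", "epilepsy")
  ep <- epoch_signal(rec, ecg = rep(1, n95))
  expect_identical(dim(ep$data), c(9L, 21L, 2560L))
  expect_identical(unique(ep$subject_ids), "s9")

  # 10-s recording: one epoch, bit-identical samples
  rec1 <- pnesentropy:::new_recording(sig[, 1:2560], fs, "s1", "PNES")
  ep1 <- epoch_signal(rec1, ecg = rep(0, 2560))
  expect_identical(ep1$data[1, "Fp1", ], unname(sig["Fp1", 1:2560]))

  # two distinct 10-s segments stay separated
  seg1 <- sin(2 * pi * 5 * seq(0, 10 - 1 / fs, by = 1 / fs))
  seg2 <- rep(2, 2560)
  sig2 <- matrix(rep(c(seg1, seg2), 22), nrow = 22, byrow = TRUE)
  rownames(sig2) <- common_channels()
  rec2 <- pnesentropy:::new_recording(sig2, fs, "s2", "PNES")
  ep2 <- epoch_signal(rec2, ecg = rep(0, 5120))
  expect_equal(ep2$data[1, "Cz", ], seg1)
  expect_equal(ep2$data[2, "Cz", ], seg2)

  expect_error(epoch_signal(rec1, ecg = rep(0, 2560), epoch_len = 20),
               "shorter")
})

test_that("artifact rejection removes planted flat/noisy/flat-ECG epochs", {
  set.seed(5)
  E <- 12
  data <- array(rnorm(E * 3 * 512, sd = 10), c(E, 3, 512))
  ecg <- matrix(rep(generate_synthetic_ecg(2, fs, 0.5, 0, seed = 1), E),
                nrow = E, byrow = TRUE)
  data[, 3, ] <- ecg
  # plant: epochs 2,5 flat EEG; epoch 7 noisy; epoch 9 flat ECG
  data[2, 1:2, ] <- 0.1
  data[5, 1:2, ] <- 0
  data[7, 2, 100] <- 5000
  data[9, 3, ] <- 0
  es <- make_epoch_set(data, c("Fp1", "Cz", "ECG"))
  out <- reject_artifacts(es, flat_uV = 1, ptp_uV = 300, ecg_floor = 0.05)
  expect_identical(pnesentropy:::n_epochs(out$epochs), 8L)
  expect_identical(out$log$epoch, c(2L, 5L, 7L, 9L))
  expect_identical(out$log$reason, c("flat", "flat", "noisy", "flat_ecg"))
  expect_error(reject_artifacts(es, flat_uV = -1), "positive")
})

test_that("baseline correction centres per subject and channel", {
  E <- 6
  data <- array(0, c(E, 2, 100))
  data[1:3, 1, ] <- 5    # subject A offset +5
  data[4:6, 1, ] <- -3   # subject B offset -3
  data[, 2, ] <- rnorm(E * 100)
  es <- make_epoch_set(data, c("Cz", "ECG"),
                       subjects = rep(c("A", "B"), each = 3),
                       labels = rep("PNES", E))
  out <- baseline_correct(es)
  for (s in c("A", "B")) for (ch in 1:2)
    expect_lt(abs(mean(out$data[es$subject_ids == s, ch, ])), 1e-9)
  # constant-offset signal becomes exactly zero
  expect_true(all(abs(out$data[1:3, 1, ]) < 1e-12))
  # per-subject centring differs from pooled centring
  pooled <- mean(data[, 1, ])
  expect_false(isTRUE(all.equal(out$data[1, 1, 1], data[1, 1, 1] - pooled)))
})

test_that("band decomposition routes tones to their band and keeps ECG", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  E <- 2
  data <- array(0, c(E, 3, 2560))
  tone <- sin(2 * pi * 6 * t)
  data[1, 1, ] <- tone
  data[1, 2, ] <- tone
  data[2, 1:2, ] <- rnorm(2 * 2560)
  data[, 3, ] <- rnorm(E * 2560)  # stands in for the derived ECG
  es <- make_epoch_set(data, c("Cz", "Pz", "ECG"))
  bands <- decompose_bands(es)
  expect_named(bands, c("broad", "delta", "theta", "alpha", "beta", "gamma"))
  # broad is the identity pass-through
  expect_identical(bands$broad$data, es$data)
  # 6 Hz tone: >= 90% of power lands in theta, < 5% in alpha
  expect_gt(var(bands$theta$data[1, 1, ]) / var(tone), 0.9)
  expect_lt(var(bands$alpha$data[1, 1, ]) / var(tone), 0.05)
  # the ECG channel is bit-identical in every band
  for (b in names(bands))
    expect_identical(bands[[b]]$data[, 3, ], es$data[, 3, ])
})

test_that("the full chain preserves label alignment and epoch accounting", {
  cfg <- tiny_cohort_config(seed = 55)
  coh <- generate_cohort(cfg)
  pre <- preprocess_cohort(coh)
  es <- pre$bands$broad
  total <- sum(vapply(coh, function(r)
    floor(ncol(r$signal) / 2560), numeric(1)))
  expect_identical(pnesentropy:::n_epochs(es) + nrow(pre$rejection_log),
                   as.integer(total))
  expect_identical(dim(es$data)[3], 2560L)
  # labels follow subjects through the chain
  lab <- vapply(coh, `[[`, "", "class_label")
  names(lab) <- vapply(coh, `[[`, "", "subject_id")
  expect_identical(es$class_labels, unname(lab[es$subject_ids]))
  # all six bands carry identical label vectors
  for (b in names(pre$bands))
    expect_identical(pre$bands[[b]]$class_labels, es$class_labels)
})
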