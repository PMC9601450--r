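# Minimal EDF (16-bit) reader/writer for whole-second multichannel
# recordings.  The format is a 256-byte fixed-width ASCII header, one
# 256-byte header block per signal, then data records of little-endian
# int16 samples scaled between per-channel physical min/max.

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

# format a number into at most `width` ASCII characters
edf_num <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g")
    if (nchar(s) <= width) return(s)
  }
  stop("cannot format ", x, " into ", width, " characters")
}

#' Write recordings to EDF files
#'
#' One file per recording, 1-second data records, 16-bit samples scaled to
#' each channel's observed physical range.
#'
#' @param recordings a single recording or list of recordings.
#' @param path output directory (created if needed); files are named
#'   `<subject_id>.edf`.
#' @return Invisibly, the written file paths.
#' @export
write_edf <- function(recordings, path) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  vapply(recordings, function(rec) {
    fs <- rec$fs
    if (fs != round(fs)) stop("unsupported fs: ", fs, " (must be integral)")
    n <- ncol(rec$signal)
    n_rec <- floor(n / fs)
    if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
    ns <- nrow(rec$signal)
    file <- file.path(path, paste0(rec$subject_id, ".edf"))
    con <- file(file, "wb")
    on.exit(close(con))
    hdr <- paste0(
      edf_pad("0", 8),
      edf_pad(paste("X X X", rec$class_label %||% "X"), 80),
      edf_pad(paste0("Startdate 01-JAN-2020 X X X"), 80),
      "01.01.20", "00.00.00",
      edf_pad(256 * (1 + ns), 8),
      edf_pad("", 44),
      edf_pad(n_rec, 8),
      edf_pad(1, 8),
      edf_pad(ns, 4))
    writeChar(hdr, con, eos = NULL)
    phys_min <- apply(rec$signal[, 1:(n_rec * fs), drop = FALSE], 1, min)
    phys_max <- apply(rec$signal[, 1:(n_rec * fs), drop = FALSE], 1, max)
    flat <- phys_max - phys_min < 1e-12
    phys_max[flat] <- phys_min[flat] + 1
    field <- function(vals, width)
      writeChar(paste(vapply(vals, edf_pad, "", width = width),
                      collapse = ""), con, eos = NULL)
    pmin_s <- vapply(phys_min, edf_num, "")
    pmax_s <- vapply(phys_max, edf_num, "")
    field(rec$channels, 16)
    field(rep("", ns), 80)                       # transducer
    field(rep("uV", ns), 8)                      # physical dimension
    field(pmin_s, 8)
    field(pmax_s, 8)
    field(rep(-32768L, ns), 8)
    field(rep(32767L, ns), 8)
    field(rep("", ns), 80)                       # prefiltering
    field(rep(fs, ns), 8)                        # samples per record
    field(rep("", ns), 32)                       # reserved
    # use the serialized (rounded) physical range so scaling round-trips
    pmin_r <- as.numeric(pmin_s)
    pmax_r <- as.numeric(pmax_s)
    scale <- (pmax_r - pmin_r) / 65535
    for (r in seq_len(n_rec)) {
      idx <- ((r - 1) * fs + 1):(r * fs)
      dig <- round((rec$signal[, idx, drop = FALSE] - pmin_r) / scale) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
    }
    file
  }, "")
  invisible(file.path(path, paste0(
    vapply(recordings, `[[`, "", "subject_id"), ".edf")))
}

#' Read an EDF file into a recording
#'
#' @param file path to a 16-bit EDF file.
#' @param require_channels channels that must be present (default the common
#'   montage ECG leads are not enforced; pass e.g. `common_channels()`).
#' @return An `eeg_recording`.
#' @export
read_edf <- function(file, require_channels = NULL) {
  con <- file(file, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width))
  rd(8)                       # version
  patient <- rd(80)
  rd(80); rd(8); rd(8)        # recording id, dates
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per_sig <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- per_sig(16)
  per_sig(80); per_sig(8)
  pmin <- as.numeric(per_sig(8))
  pmax <- as.numeric(per_sig(8))
  dmin <- as.numeric(per_sig(8))
  dmax <- as.numeric(per_sig(8))
  per_sig(80)
  spr <- as.integer(per_sig(8))
  per_sig(32)
  if (length(unique(spr)) != 1)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[1] / dur
  if (fs != round(fs)) stop("unsupported fs: ", fs)
  n <- n_rec * spr[1]
  sig <- matrix(0, ns, n, dimnames = list(labels, NULL))
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    sig[, idx] <- t(block - dmin) * scale + pmin
  }
  if (!is.null(require_channels)) {
    missing <- setdiff(require_channels, labels)
    if (length(missing))
      stop("EDF file missing channel(s): ", paste(missing, collapse = ", "))
  }
  label <- sub("^X X X ?", "", patient)
  if (label == "X" || label == "") label <- NA_character_
  new_recording(sig, fs,
                subject_id = sub("\\.edf$", "", basename(file)),
                class_label = label)
}
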