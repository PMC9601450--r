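#' EEG frequency band definitions
#'
#' The analysis bands: broad 0.5--40 Hz, delta 0.5--4 Hz, theta 4--8 Hz,
#' alpha 8--13 Hz, beta 13--30 Hz, gamma 30--40 Hz.
#'
#' @param names optional character vector restricting which bands are
#'   returned (in the given order).
#' @return A data frame with columns `name`, `low`, `high` (Hz).
#' @export
#' @examples
#' eeg_bands()
#' eeg_bands(c("theta", "alpha"))
eeg_bands <- function(names = NULL) {
  bands <- data.frame(
    name = c("broad", "delta", "theta", "alpha", "beta", "gamma"),
    low  = c(0.5, 0.5, 4, 8, 13, 30),
    high = c(40, 4, 8, 13, 30, 40),
    stringsAsFactors = FALSE
  )
  if (is.null(names)) return(bands)
  unknown <- setdiff(names, bands$name)
  if (length(unknown))
    stop("unknown band(s): ", paste(unknown, collapse = ", "))
  bands[match(names, bands$name), , drop = FALSE]
}

# Non-broad bands in canonical order.
narrow_band_names <- function() c("delta", "theta", "alpha", "beta", "gamma")

#' Common electrode montage
#'
#' The 10--20 montage channel set retained after resampling: 20 scalp EEG
#' electrodes plus the two ECG leads.
#'
#' @return Character vector of 22 channel names.
#' @export
common_channels <- function() {
  c("Fp1", "F7", "T3", "T5", "O1", "F3", "C3", "P3", "Fz", "Cz",
    "Fp2", "F8", "T4", "T6", "O2", "F4", "C4", "P4", "Fpz", "Pz",
    "ECG+", "ECG-")
}

eeg_channel_names <- function() setdiff(common_channels(), c("ECG+", "ECG-"))
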