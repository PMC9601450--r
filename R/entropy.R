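# Six entropy estimators.  Approximate and sample entropy use the compiled
# template-matching kernels (Chebyshev distance, absolute tolerance r);
# everything here is computed per channel per epoch.

#' Parameters for the entropy estimators
#'
#' @param m run (template) length for approximate/sample entropy (1 or 2).
#' @param r_sd tolerance multiplier: r = r_sd * SD of the series, with the
#'   SD computed per epoch per channel.
#' @param alpha Renyi order (>= 0, != 1).
#' @param n_hist_bins equal-width amplitude histogram bins for Renyi entropy.
#' @param svd_emb,svd_tau delay-embedding dimension and delay for SVD entropy.
#' @param welch_seg_sec,welch_overlap Welch segment length (s) and overlap
#'   fraction for spectral entropy.
#' @param wavelet_scales number of log-spaced Morlet scales.
#' @param wavelet_fmin,wavelet_fmax frequency range covered by the scales (Hz).
#' @param apen_m,apen_r_sd,sampen_m,sampen_r_sd measure-specific overrides of
#'   `m`/`r_sd` (defaults: the grid-search selections m=2, r_sd=0.2 for ApEn
#'   and m=1, r_sd=0.15 for SampEn).
#' @return List of class `entropy_params`.
#' @export
entropy_params <- function(m = 2, r_sd = 0.2, alpha = 2, n_hist_bins = 100,
                           svd_emb = 10, svd_tau = 2,
                           welch_seg_sec = 1, welch_overlap = 0.5,
                           wavelet_scales = 10, wavelet_fmin = 0.5,
                           wavelet_fmax = 40,
                           apen_m = 2, apen_r_sd = 0.2,
                           sampen_m = 1, sampen_r_sd = 0.15) {
  stopifnot(m %in% 1:2, r_sd > 0, alpha >= 0, alpha != 1,
            n_hist_bins >= 2, svd_emb >= 2, svd_tau >= 1,
            wavelet_scales >= 2)
  structure(as.list(environment()), class = "entropy_params")
}

check_series <- function(x) {
  if (any(!is.finite(x))) stop("series contains non-finite values")
  x
}

#' Approximate entropy
#'
#' Template-counting regularity statistic with self-matches included:
#' ApEn(m, r, N) = Phi^m(r) - Phi^(m+1)(r), where Phi^m is the mean natural
#' log of the fraction of templates within Chebyshev distance r.
#'
#' @param x numeric series.
#' @param m run length.
#' @param r absolute tolerance; if `NULL`, computed as `r_sd * sd(x)`.
#' @param r_sd tolerance multiplier used when `r` is `NULL`.
#' @return Non-negative scalar.  A zero-variance series returns 0 with a
#'   warning (a flat channel carries no irregularity).
#' @export
approximate_entropy <- function(x, m = 2, r = NULL, r_sd = 0.2) {
  check_series(x)
  if (is.null(r)) {
    s <- stats::sd(x)
    if (s == 0) {
      warning("zero-variance series: approximate entropy set to 0")
      return(0)
    }
    r <- r_sd * s
  }
  apen_cpp(x, as.integer(m), r)
}

#' Sample entropy
#'
#' As [approximate_entropy()] but excluding self-matches:
#' SampEn(m, r, N) = -ln(A/B) with B and A the m- and (m+1)-template match
#' probabilities.  If no template pair matches (A or B zero) the statistic is
#' undefined and `NaN` is returned.
#'
#' @inheritParams approximate_entropy
#' @export
sample_entropy <- function(x, m = 1, r = NULL, r_sd = 0.15) {
  check_series(x)
  if (is.null(r)) {
    s <- stats::sd(x)
    if (s == 0) {
      warning("zero-variance series: sample entropy set to 0")
      return(0)
    }
    r <- r_sd * s
  }
  out <- sampen_cpp(x, as.integer(m), r)
  if (is.na(out)) NaN else out
}

#' Welch power spectral density
#'
#' Hamming-windowed, overlapping segments, one-sided density.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param seg_sec segment length in seconds.
#' @param overlap overlap fraction in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_sec = 1, overlap = 0.5) {
  nseg <- round(seg_sec * fs)
  if (length(x) < nseg) stop("series shorter than one Welch segment")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    X <- stats::fft((seg - mean(seg)) * w)
    p <- (Mod(X)^2 * scale)[1:nfreq]
    acc <- acc + p
  }
  psd <- acc / length(starts)
  if (nseg %% 2 == 0) psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  else psd[2:nfreq] <- 2 * psd[2:nfreq]
  list(freq = (0:(nfreq - 1)) * fs / nseg, psd = psd)
}

#' Shannon entropy of a discrete distribution
#'
#' @param p probability vector (normalized internally); zero bins contribute 0.
#' @param base logarithm base.
#' @param normalize divide by log(number of states) so the maximum is 1.
#' @export
discrete_shannon <- function(p, base = exp(1), normalize = FALSE) {
  if (any(p < 0)) stop("negative probabilities")
  tot <- sum(p)
  if (tot <= 0) stop("zero-mass distribution")
  p <- p / tot
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz], base = base))
  if (normalize) h <- h / log(length(p), base = base)
  h
}

#' Renyi entropy of a discrete distribution
#'
#' @param p probability vector (normalized internally).
#' @param alpha order (>= 0, != 1); log base 2.
#' @export
discrete_renyi <- function(p, alpha = 2) {
  if (alpha < 0 || alpha == 1) stop("alpha must be >= 0 and != 1")
  tot <- sum(p)
  if (tot <= 0) stop("zero-mass distribution")
  p <- p / tot
  log2(sum(p[p > 0]^alpha)) / (1 - alpha)
}

#' Spectral entropy
#'
#' Shannon entropy of the Welch PSD normalized to a probability vector,
#' divided by ln(number of PSD bins); lies in `[0, 1]`.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param seg_sec,overlap Welch parameters.
#' @export
spectral_entropy <- function(x, fs, seg_sec = 1, overlap = 0.5) {
  check_series(x)
  if (all(x == 0)) stop("all-zero signal: spectrum undefined")
  ps <- welch_psd(x, fs, seg_sec, overlap)
  discrete_shannon(ps$psd, normalize = TRUE)
}

#' SVD entropy
#'
#' Shannon entropy (base 2, normalized) of the squared singular values of
#' the delay-embedding (Hankel-structured) matrix of the series; lies in
#' `[0, 1]`.
#'
#' @param x numeric series.
#' @param emb embedding dimension.
#' @param tau embedding delay.
#' @export
svd_entropy <- function(x, emb = 10, tau = 2) {
  check_series(x)
  if (all(x == 0)) stop("all-zero series: SVD entropy undefined")
  n <- length(x) - (emb - 1) * tau
  if (n < emb) stop("series too short for embedding (need >= emb*tau)")
  Y <- sapply(seq_len(emb), function(k) x[(0:(n - 1)) + 1 + (k - 1) * tau])
  d <- svd(Y, nu = 0, nv = 0)$d
  p <- d^2 / sum(d^2)
  L <- length(d)
  nz <- p > 0
  -sum(p[nz] * log2(p[nz])) / log2(L)
}

#' Renyi entropy of a series
#'
#' The amplitude distribution is estimated with an equal-width histogram
#' over the observed range (`n_bins` bins), then the order-`alpha` Renyi
#' entropy (base 2) is computed.  Lies in `[0, log2(n_bins)]`.
#'
#' @param x numeric series.
#' @param alpha Renyi order.
#' @param n_bins histogram bin count.
#' @export
renyi_entropy <- function(x, alpha = 2, n_bins = 100) {
  check_series(x)
  rng <- range(x)
  if (diff(rng) == 0) return(0)  # single occupied bin
  width <- diff(rng) / n_bins
  idx <- pmin(floor((x - rng[1]) / width) + 1L, n_bins)
  p <- tabulate(idx, n_bins) / length(x)
  discrete_renyi(p, alpha)
}

#' Morlet continuous wavelet transform
#'
#' Analytic Morlet wavelet (centre frequency `omega0` rad), evaluated in
#' the frequency domain at the requested centre frequencies.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param freqs centre frequencies (Hz).
#' @param omega0 wavelet centre frequency in radians (default 6).
#' @return Complex matrix, length(x) rows x length(freqs) columns.
#' @export
morlet_cwt <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  w <- 2 * pi * (0:(nfft - 1)) / nfft            # rad/sample
  w[w > pi] <- w[w > pi] - 2 * pi
  out <- matrix(0i, n, length(freqs))
  for (j in seq_along(freqs)) {
    s <- omega0 * fs / (2 * pi * freqs[j])       # scale in samples
    psi <- numeric(nfft)
    pos <- w > 0
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s) * exp(-(s * w[pos] - omega0)^2 / 2)
    out[, j] <- stats::fft(X * psi, inverse = TRUE)[1:n] / nfft
  }
  out
}

#' Wavelet entropy
#'
#' Shannon entropy (natural log) of the relative Morlet wavelet energies
#' across scales, with energies averaged over the analysis window (default:
#' the whole epoch, giving one value per epoch).  Lies in `[0, ln J]`.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param n_scales number of log-spaced scales J.
#' @param fmin,fmax frequency range covered (Hz).
#' @param window window length Delta-t in seconds; `NULL` uses the whole
#'   epoch.  With a window, the mean entropy over successive windows is
#'   returned.
#' @export
wavelet_entropy <- function(x, fs, n_scales = 10, fmin = 0.5, fmax = 40,
                            window = NULL) {
  check_series(x)
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n_scales))
  E <- Mod(morlet_cwt(x, fs, freqs))^2
  if (sum(E) == 0) stop("zero total wavelet energy")
  ent_of <- function(rows) {
    ej <- colMeans(E[rows, , drop = FALSE])
    discrete_shannon(ej)
  }
  if (is.null(window)) return(ent_of(seq_len(nrow(E))))
  len <- round(window * fs)
  n_win <- floor(nrow(E) / len)
  if (n_win < 1) stop("window longer than the series")
  mean(vapply(seq_len(n_win), function(k)
    ent_of(((k - 1) * len + 1):(k * len)), 0))
}
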