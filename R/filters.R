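# Zero-phase filtering utilities shared by the preprocessing chain.
#
# All band filters are applied forward-backward (zero phase) so the epochs of
# different bands stay time-aligned.  FIR filtering is done in the frequency
# domain on reflection-padded signals, batched over columns, which keeps the
# per-epoch band decomposition affordable for long (Hamming) kernels.

# Hamming-window FIR bandpass design.  Transition bandwidths follow the rule
# trans = min(max(0.25 * f, 2 Hz), headroom) at each edge; the kernel length
# is set by the narrower transition (3.3 / trans cycles).
fir_bandpass <- function(low, high, fs) {
  if (low <= 0 || high >= fs / 2 || low >= high)
    stop("cutoffs must satisfy 0 < low < high < fs/2 (got ",
         low, ", ", high, " at fs = ", fs, ")")
  trans_l <- min(max(0.25 * low, 2), low)
  trans_h <- min(max(0.25 * high, 2), fs / 2 - high)
  trans <- min(trans_l, trans_h)
  ntaps <- ceiling(3.3 * fs / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1  # odd length, type-I linear phase
  signal::fir1(ntaps - 1, c(low, high) / (fs / 2), type = "pass")
}

fir_lowpass <- function(cutoff, fs, trans = NULL) {
  trans <- trans %||% min(max(0.25 * cutoff, 2), fs / 2 - cutoff)
  ntaps <- ceiling(3.3 * fs / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  signal::fir1(ntaps - 1, cutoff / (fs / 2), type = "low")
}

# Zero-phase FIR filtering via FFT: equivalent to filtering forward and
# backward with kernel h (frequency response |H|^2).  `x` may be a vector or
# a samples-by-series matrix.  Edges are odd-reflection padded, as in
# conventional filtfilt implementations.
fft_filtfilt <- function(x, h) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  p <- length(h)
  pad <- min(p, n - 1)
  top <- 2 * X[rep(1L, pad), , drop = FALSE] - X[(pad + 1):2, , drop = FALSE]
  bot <- 2 * X[rep(n, pad), , drop = FALSE] -
    X[(n - 1):(n - pad), , drop = FALSE]
  Xp <- rbind(top, X, bot)
  np <- nrow(Xp)
  # wrap-around of the zero-phase kernel (support +-(p-1)) stays inside the
  # discarded reflection pads as long as nfft >= np and pad >= p - 1
  nfft <- stats::nextn(np, 2)
  H <- stats::fft(c(h, numeric(nfft - p)))
  mag2 <- Re(H * Conj(H))
  Xf <- stats::mvfft(rbind(Xp, matrix(0, nfft - np, ncol(Xp))))
  Y <- Re(stats::mvfft(Xf * mag2, inverse = TRUE)) / nfft
  out <- Y[(pad + 1):(pad + n), , drop = FALSE]
  if (vec) drop(out) else out
}

# Apply several zero-phase FIR kernels to the same set of series, sharing
# the forward FFT (compiled path).  `X` is samples x series; returns one
# filtered matrix per kernel.
multiband_filtfilt <- function(X, kernels) {
  multiband_filtfilt_cpp(X, kernels)
}

# ---- Bessel IIR design -----------------------------------------------------

# Analog Bessel lowpass prototype: poles of the reverse Bessel polynomial,
# rescaled so the -3 dB point sits at 1 rad/s; unit DC gain.
bessel_proto <- function(n) {
  k <- 0:n
  coef <- factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
  p <- polyroot(coef)  # ascending-power coefficients
  magsq <- function(w) {
    h <- coef[1] / apply(outer(1i * w, p, "-"), 1, prod)
    Mod(h)^2
  }
  w3 <- stats::uniroot(function(w) magsq(w) - 0.5, c(1e-3, 10),
                       tol = 1e-12)$root
  p <- p / w3
  list(pole = p, gain = Re(prod(-p)))
}

# Digital Bessel filter via analog prototype + frequency transform +
# bilinear transform with prewarping.  Returned as a cascade of biquad
# sections: with cutoffs as low as 0.25 Hz the poles sit so close to z = 1
# that a single transfer-function polynomial is numerically unusable.
bessel_filter <- function(n, W, fs, type = c("pass", "high", "low")) {
  type <- match.arg(type)
  if (any(W <= 0) || any(W >= fs / 2))
    stop("Bessel cutoffs must lie in (0, fs/2); got ",
         paste(W, collapse = ", "))
  proto <- bessel_proto(n)
  Tbl <- 2
  warped <- (2 / Tbl) * tan(pi * (W / (fs / 2)) / Tbl)
  Sz <- signal::Zpg(pole = proto$pole, zero = complex(0), gain = proto$gain)
  Sz <- switch(type,
    pass = signal::sftrans(Sz, W = warped, stop = FALSE),
    high = signal::sftrans(Sz, W = warped, stop = TRUE),
    low  = signal::sftrans(Sz, W = warped, stop = FALSE))
  Zz <- signal::bilinear(Sz, T = Tbl)
  zpg_to_sos(Zz$zero, Zz$pole, Zz$gain)
}

# Group zeros/poles into second-order sections.  Conjugate pairs are kept
# together; pole pairs closest to the unit circle are matched with their
# nearest zero pair.  Gain is folded into the first section.
zpg_to_sos <- function(zeros, poles, gain) {
  pair_up <- function(v) {
    cplx <- v[Im(v) > 1e-8]  # one representative per conjugate pair
    reals <- sort(Re(v[abs(Im(v)) <= 1e-8]))
    if (length(reals) %% 2 == 1) stop("odd number of real roots")
    pairs <- lapply(cplx, function(z) c(z, Conj(z)))
    if (length(reals))
      pairs <- c(pairs, lapply(seq(1, length(reals), by = 2), function(i)
        complex(real = reals[i + 0:1], imaginary = 0)))
    pairs
  }
  zp <- pair_up(zeros)
  pp <- pair_up(poles)
  if (length(zp) != length(pp))
    stop("zero/pole pair mismatch (orders must be even)")
  # sections ordered by pole distance to unit circle (closest first)
  pp <- pp[order(vapply(pp, function(p) min(1 - Mod(p)), 0))]
  used <- logical(length(zp))
  sos <- vector("list", length(pp))
  for (s in seq_along(pp)) {
    d <- vapply(seq_along(zp), function(i) {
      if (used[i]) return(Inf)
      min(Mod(zp[[i]][1] - pp[[s]][1]), Mod(zp[[i]][1] - pp[[s]][2]))
    }, 0)
    i <- which.min(d)
    used[i] <- TRUE
    b <- Re(c(1, -(zp[[i]][1] + zp[[i]][2]), zp[[i]][1] * zp[[i]][2]))
    a <- Re(c(1, -(pp[[s]][1] + pp[[s]][2]), pp[[s]][1] * pp[[s]][2]))
    sos[[s]] <- list(b = b, a = a)
  }
  sos[[1]]$b <- sos[[1]]$b * Re(gain)
  structure(sos, class = "sos_filter")
}

# Zero-phase IIR filtering (forward-backward), section by section, for
# vectors or sample-major matrices.
iir_filtfilt <- function(x, filt) {
  f1 <- function(v) {
    if (inherits(filt, "sos_filter")) {
      for (sec in filt)
        v <- signal::filtfilt(signal::Arma(b = sec$b, a = sec$a), v)
      v
    } else signal::filtfilt(filt, v)
  }
  if (is.null(dim(x))) f1(x) else apply(x, 2, f1)
}
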