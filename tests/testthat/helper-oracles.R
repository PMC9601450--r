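# Independent brute-force oracles, written directly from the estimator
# definitions.  They share no code with the package implementations.

# Approximate entropy: Phi^m - Phi^(m+1), self-matches included,
# Chebyshev distance, natural log.
apen_oracle <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    nt <- N - mm + 1
    logs <- vapply(seq_len(nt), function(i) {
      d <- numeric(nt)
      for (k in 0:(mm - 1)) d <- pmax(d, abs(x[i + k] - x[seq_len(nt) + k]))
      log(sum(d <= r) / nt)
    }, 0)
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Sample entropy: -ln(A/B), self-matches excluded, both template sets of
# size N - m.
sampen_oracle <- function(x, m, r) {
  N <- length(x)
  n <- N - m
  count_pairs <- function(mm) {
    tot <- 0
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      d <- numeric(length(js))
      for (k in 0:(mm - 1)) d <- pmax(d, abs(x[i + k] - x[js + k]))
      tot <- tot + sum(d <= r)
    }
    tot
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1)
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

# Spectral entropy oracle: independent Welch estimate (plain loops) and
# direct PSD normalization.
specen_oracle <- function(x, fs, seg_sec = 1, overlap = 0.5) {
  nseg <- round(seg_sec * fs)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  starts <- seq(1, length(x) - nseg + 1, by = round(nseg * (1 - overlap)))
  nfreq <- nseg %/% 2 + 1
  P <- matrix(0, length(starts), nfreq)
  for (q in seq_along(starts)) {
    seg <- x[starts[q]:(starts[q] + nseg - 1)]
    seg <- seg - mean(seg)
    X <- fft(seg * w)
    P[q, ] <- Mod(X[1:nfreq])^2
  }
  psd <- colMeans(P)
  if (nseg %% 2 == 0) psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  else psd[2:nfreq] <- 2 * psd[2:nfreq]
  p <- psd / sum(psd)
  p <- p[p > 0]
  -sum(p * log(p)) / log(nfreq)
}

# SVD entropy oracle: eigenvalues of the Gram matrix of the delay
# embedding, independent eigen-solver.
svden_oracle <- function(x, emb, tau) {
  n <- length(x) - (emb - 1) * tau
  Y <- matrix(0, n, emb)
  for (k in seq_len(emb)) Y[, k] <- x[(0:(n - 1)) + 1 + (k - 1) * tau]
  ev <- eigen(crossprod(Y), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  p <- ev / sum(ev)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(min(emb, n))
}

# Renyi entropy oracle: histogram via hist() on the same equal-width
# breaks, direct formula with base-2 log.
renyi_oracle <- function(x, alpha = 2, n_bins = 100) {
  if (diff(range(x)) == 0) return(0)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  cnt <- hist(x, breaks = breaks, plot = FALSE, right = FALSE,
              include.lowest = TRUE)$counts
  # hist(right = FALSE) puts the maximum in the last bin, matching the
  # implementation's clamp of the top edge
  p <- cnt / length(x)
  log2(sum(p^alpha)) / (1 - alpha)
}

# Wavelet entropy oracle: direct energy accounting over the package's
# Morlet coefficients (the CWT itself is checked separately against known
# tone locations).
waveen_oracle <- function(x, fs, n_scales = 10, fmin = 0.5, fmax = 40) {
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n_scales))
  C <- morlet_cwt(x, fs, freqs)
  E <- colSums(Mod(C)^2)
  p <- E / sum(E)
  p <- p[p > 0]
  -sum(p * log(p))
}

# PCA reconstruction oracle: eigen decomposition of the covariance matrix.
pca_oracle_ncomp <- function(X, variance) {
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  cum <- cumsum(ev) / sum(ev)
  which(cum >= variance)[1]
}
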