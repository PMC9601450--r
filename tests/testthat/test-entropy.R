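test_that("constant and degenerate series hit the analytic limits", {
  const <- rep(2.5, 300)
  expect_warning(a <- approximate_entropy(const, m = 2), "zero-variance")
  expect_identical(a, 0)
  expect_warning(s <- sample_entropy(const, m = 1), "zero-variance")
  expect_identical(s, 0)
  # constant with explicit r > 0: all templates match, entropy 0
  expect_equal(approximate_entropy(const, m = 2, r = 0.1), 0)
  expect_equal(sample_entropy(const, m = 1, r = 0.1), 0)
  # rank-1 embedding: SVD entropy 0
  expect_lt(svd_entropy(rep(3, 200), emb = 4, tau = 1), 1e-12)
  expect_error(svd_entropy(rep(0, 200)), "all-zero")
  # single occupied histogram bin: Renyi 0
  expect_identical(renyi_entropy(rep(1, 100)), 0)
  expect_error(spectral_entropy(rep(0, 512), 256), "all-zero")
})

test_that("discrete entropy helpers match their closed forms", {
  Om <- 64
  expect_equal(discrete_shannon(rep(1 / Om, Om), normalize = TRUE), 1)
  expect_equal(discrete_shannon(c(1, rep(0, Om - 1)), normalize = TRUE), 0)
  expect_equal(discrete_shannon(c(0.5, 0.5, rep(0, Om - 2)),
                                normalize = TRUE), log(2) / log(Om))
  expect_equal(discrete_renyi(rep(1 / Om, Om), 2), log2(Om))
  expect_equal(discrete_renyi(c(1, rep(0, 3)), 2), 0)
  expect_equal(discrete_renyi(c(0.5, 0.25, 0.25), 2), -log2(0.375))
  expect_error(discrete_renyi(c(0.5, 0.5), 1), "alpha")
})

test_that("estimators match their brute-force oracles on random series", {
  set.seed(71)
  for (k in 1:4) {
    x <- as.numeric(arima.sim(list(ar = 0.6), 400))
    r <- 0.2 * sd(x)
    expect_lt(abs(approximate_entropy(x, 2, r) - apen_oracle(x, 2, r)),
              1e-10)
    expect_lt(abs(approximate_entropy(x, 1, r) - apen_oracle(x, 1, r)),
              1e-10)
    expect_lt(abs(sample_entropy(x, 1, r) - sampen_oracle(x, 1, r)), 1e-10)
    expect_lt(abs(sample_entropy(x, 2, r) - sampen_oracle(x, 2, r)), 1e-10)
    expect_lt(abs(svd_entropy(x, 10, 2) - svden_oracle(x, 10, 2)), 1e-8)
    expect_lt(abs(renyi_entropy(x) - renyi_oracle(x)), 1e-10)
  }
})

test_that("the combined grid kernel agrees with the single-cell kernels", {
  set.seed(72)
  x <- rnorm(500)
  r_sds <- c(0.1, 0.15, 0.2, 0.25)
  g <- pnesentropy:::apen_sampen_grid_cpp(x, r_sds * sd(x))
  for (q in seq_along(r_sds)) {
    r <- r_sds[q] * sd(x)
    expect_equal(unname(g["apen_m1", q]), approximate_entropy(x, 1, r))
    expect_equal(unname(g["apen_m2", q]), approximate_entropy(x, 2, r))
    expect_equal(unname(g["sampen_m1", q]), sample_entropy(x, 1, r))
    expect_equal(unname(g["sampen_m2", q]), sample_entropy(x, 2, r))
  }
})

test_that("sample entropy is invariant to scaling under the r_sd rule", {
  set.seed(73)
  x <- rnorm(400)
  expect_equal(sample_entropy(x, 1, r_sd = 0.15),
               sample_entropy(7.3 * x, 1, r_sd = 0.15))
  expect_equal(approximate_entropy(x, 2, r_sd = 0.2),
               approximate_entropy(7.3 * x, 2, r_sd = 0.2))
})

test_that("sample entropy returns NaN when no templates match", {
  x <- as.numeric(1:50)  # monotone ramp: no Chebyshev matches at tiny r
  expect_true(is.nan(sample_entropy(x, 1, r = 0.1)))
})

test_that("white noise scores higher than a matched-variance sinusoid", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  wins <- 0
  for (s in 1:8) {
    set.seed(s)
    tone <- sin(2 * pi * 5 * t + runif(1, 0, 2 * pi))
    noise <- rnorm(length(t), sd = sd(tone))
    ok <- sample_entropy(noise, 1, r_sd = 0.15) >
      sample_entropy(tone, 1, r_sd = 0.15) &&
      approximate_entropy(noise, 2, r_sd = 0.2) >
        approximate_entropy(tone, 2, r_sd = 0.2) &&
      spectral_entropy(noise, fs) > spectral_entropy(tone, fs) &&
      wavelet_entropy(noise, fs) > wavelet_entropy(tone, fs)
    wins <- wins + ok
  }
  expect_gte(wins, 7)
})

test_that("normalized estimators stay in their ranges", {
  set.seed(74)
  for (k in 1:10) {
    x <- as.numeric(arima.sim(list(ar = runif(1, -0.5, 0.9)), 512))
    expect_true(spectral_entropy(x, 256) >= 0 &&
                  spectral_entropy(x, 256) <= 1)
    expect_true(svd_entropy(x) >= 0 && svd_entropy(x) <= 1)
    expect_true(renyi_entropy(x, 2, 100) >= 0 &&
                  renyi_entropy(x, 2, 100) <= log2(100))
    w <- wavelet_entropy(x, 256)
    expect_true(w >= 0 && w <= log(10))
  }
})

test_that("Morlet energies peak at the tone's frequency", {
  fs <- 256
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  freqs <- exp(seq(log(2), log(32), length.out = 12))
  C <- morlet_cwt(sin(2 * pi * 6 * t), fs, freqs)
  E <- colSums(Mod(C)^2)
  expect_equal(which.max(E), which.min(abs(freqs - 6)))
})

test_that("wavelet entropy matches direct energy accounting", {
  set.seed(75)
  x <- rnorm(1024)
  expect_lt(abs(wavelet_entropy(x, 256) - waveen_oracle(x, 256)), 1e-10)
  # windowed variant returns the mean over complete windows
  w <- wavelet_entropy(x, 256, window = 2)
  expect_true(is.finite(w) && w <= log(10))
})

test_that("SampEn of an i.i.d. process is stable across disjoint epochs", {
  set.seed(76)
  vals <- vapply(1:20, function(k)
    sample_entropy(rnorm(2560), m = 1, r_sd = 0.15), 0)
  expect_lt(sd(vals) / mean(vals), 0.15)
})

test_that("feature extraction produces annotated matrices", {
  cfg <- tiny_cohort_config(seed = 91)
  pre <- preprocess_cohort(generate_cohort(cfg))
  E <- pnesentropy:::n_epochs(pre$bands$broad)

  fm1 <- extract_features(pre$bands["theta"], "renyi")
  expect_identical(dim(fm1$X), c(E, 21L))
  expect_identical(unique(fm1$groups), "theta")

  fm6 <- extract_features(pre$bands, "renyi")
  expect_identical(dim(fm6$X), c(E, 126L))
  expect_identical(as.vector(table(fm6$groups)[unique(fm6$groups)]),
                   rep(21L, 6))
  expect_false(any(!is.finite(fm6$X)))
  # determinism: identical epochs give identical rows
  dup <- pre$bands["theta"]
  dup$theta$data[2, , ] <- dup$theta$data[1, , ]
  fmd <- extract_features(dup, "renyi")
  expect_identical(fmd$X[1, ], fmd$X[2, ])
  # feature matrix round-trips through TSV
  path <- tempfile(fileext = ".tsv")
  write_features_tsv(fm1, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -(1:2)]), fm1$X, ignore_attr = TRUE,
               tolerance = 1e-6)
})
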