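#include <Rcpp.h>
using namespace Rcpp;

// Template-matching kernels for approximate and sample entropy.
// Distances are Chebyshev (max over scalar components); tolerances r are
// absolute (already scaled by the caller as r_sd * SD of the series).

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  if (N <= m + 1) stop("series too short for m = %d", m);
  if (r <= 0) stop("tolerance r must be positive");
  // counts for template lengths m and m+1 (self-match included via init 1)
  const int n_m = N - m + 1, n_m1 = N - m;
  std::vector<int> cm(n_m, 1), cm1(n_m1, 1);
  for (int i = 0; i < n_m; ++i) {
    for (int j = i + 1; j < n_m; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) { cm[i]++; cm[j]++; }
      if (i < n_m1 && j < n_m1) {
        double dk = std::fabs(x[i + m] - x[j + m]);
        if (dk > d) d = dk;
        if (d <= r) { cm1[i]++; cm1[j]++; }
      }
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < n_m; ++i)  phi_m  += std::log((double)cm[i]  / n_m);
  for (int i = 0; i < n_m1; ++i) phi_m1 += std::log((double)cm1[i] / n_m1);
  phi_m /= n_m;
  phi_m1 /= n_m1;
  return phi_m - phi_m1;
}

// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  if (N <= m + 1) stop("series too short for m = %d", m);
  if (r <= 0) stop("tolerance r must be positive");
  // both template sets indexed i = 1..N-m (0..N-m-1); self-matches excluded
  const int n = N - m;
  long long B = 0, A = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B++;
        double dk = std::fabs(x[i + m] - x[j + m]);
        if (dk > d) d = dk;
        if (d <= r) A++;
      }
    }
  }
  if (A == 0 || B == 0) return NA_REAL;  // degenerate: -ln(A/B) undefined
  return -std::log((double)A / (double)B);
}

// One O(N^2) pass computing ApEn (m = 1, 2) and SampEn (m = 1, 2) for a
// vector of absolute tolerances.  Used by the (m, r_sd) grid search so the
// eight grid cells cost a single pairwise sweep per series.
// Returns a matrix with rows (apen_m1, apen_m2, sampen_m1, sampen_m2) and
// one column per tolerance.
// [[Rcpp::export]]
NumericMatrix apen_sampen_grid_cpp(NumericVector x, NumericVector rvec) {
  const int N = x.size(), nr = rvec.size();
  if (N < 8) stop("series too short");
  for (int q = 0; q < nr; ++q)
    if (rvec[q] <= 0) stop("tolerance r must be positive");
  // per-template counts for lengths 1..3 (ApEn, self-match via init 1)
  std::vector<std::vector<int>> c1(nr, std::vector<int>(N, 1));
  std::vector<std::vector<int>> c2(nr, std::vector<int>(N - 1, 1));
  std::vector<std::vector<int>> c3(nr, std::vector<int>(N - 2, 1));
  // SampEn pair totals: m=1 templates i<=N-1; m=2 templates i<=N-2
  std::vector<long long> B1(nr, 0), A1(nr, 0), B2(nr, 0), A2(nr, 0);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d1 = std::fabs(x[i] - x[j]);
      double d2 = -1.0, d3 = -1.0;
      bool in2 = (j < N - 1), in3 = (j < N - 2);
      if (in2) {
        d2 = std::fabs(x[i + 1] - x[j + 1]);
        if (d1 > d2) d2 = d1;
        if (in3) {
          d3 = std::fabs(x[i + 2] - x[j + 2]);
          if (d2 > d3) d3 = d2;
        }
      }
      for (int q = 0; q < nr; ++q) {
        const double r = rvec[q];
        if (d1 <= r) {
          c1[q][i]++; c1[q][j]++;
          if (in2) B1[q]++;
        }
        if (in2 && d2 <= r) {
          c2[q][i]++; c2[q][j]++;
          A1[q]++;
          if (in3) B2[q]++;
        }
        if (in3 && d3 <= r) {
          c3[q][i]++; c3[q][j]++;
          A2[q]++;
        }
      }
    }
  }
  NumericMatrix out(4, nr);
  rownames(out) = CharacterVector::create("apen_m1", "apen_m2",
                                          "sampen_m1", "sampen_m2");
  for (int q = 0; q < nr; ++q) {
    double phi1 = 0.0, phi2 = 0.0, phi3 = 0.0;
    for (int i = 0; i < N; ++i)     phi1 += std::log((double)c1[q][i] / N);
    for (int i = 0; i < N - 1; ++i) phi2 += std::log((double)c2[q][i] / (N - 1));
    for (int i = 0; i < N - 2; ++i) phi3 += std::log((double)c3[q][i] / (N - 2));
    phi1 /= N; phi2 /= (N - 1); phi3 /= (N - 2);
    out(0, q) = phi1 - phi2;
    out(1, q) = phi2 - phi3;
    out(2, q) = (A1[q] == 0 || B1[q] == 0) ? NA_REAL
                : -std::log((double)A1[q] / (double)B1[q]);
    out(3, q) = (A2[q] == 0 || B2[q] == 0) ? NA_REAL
                : -std::log((double)A2[q] / (double)B2[q]);
  }
  return out;
}

// Order-alpha Renyi entropy (base-2 log) of each column of X via an
// equal-width amplitude histogram over that column's observed range.
// [[Rcpp::export]]
NumericVector renyi_matrix_cpp(NumericMatrix X, double alpha, int nbins) {
  const int n = X.nrow(), nc = X.ncol();
  NumericVector out(nc);
  std::vector<int> counts(nbins);
  for (int j = 0; j < nc; ++j) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double v = X(i, j);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    if (!(hi > lo)) { out[j] = 0.0; continue; }
    const double w = (hi - lo) / nbins;
    std::fill(counts.begin(), counts.end(), 0);
    for (int i = 0; i < n; ++i) {
      int k = (int)((X(i, j) - lo) / w);
      if (k >= nbins) k = nbins - 1;
      counts[k]++;
    }
    double acc = 0.0;
    for (int k = 0; k < nbins; ++k)
      if (counts[k] > 0) acc += std::pow((double)counts[k] / n, alpha);
    out[j] = std::log2(acc) / (1.0 - alpha);
  }
  return out;
}
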