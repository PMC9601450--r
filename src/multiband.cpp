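// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Zero-phase FIR filtering of the columns of X with several kernels at
// once, sharing the forward FFT.  Equivalent to filtering forward and
// backward with each kernel (frequency response |H|^2); edges are
// odd-reflection padded.  Pairs of real columns are packed into single
// complex FFT columns, and FFTs run on column blocks to bound memory.
// [[Rcpp::export]]
List multiband_filtfilt_cpp(const arma::mat& X, List kernels) {
  const int n = X.n_rows, nc = X.n_cols, nb = kernels.size();
  int p = 0;
  for (int b = 0; b < nb; ++b)
    p = std::max(p, (int)as<NumericVector>(kernels[b]).size());
  const int pad = std::min(p, n - 1);
  const int np = n + 2 * pad;
  int nfft = 1;
  while (nfft < np) nfft <<= 1;

  // |H|^2 per kernel at nfft
  arma::mat mags(nfft, nb);
  for (int b = 0; b < nb; ++b) {
    NumericVector h = kernels[b];
    arma::cx_vec hv(nfft, arma::fill::zeros);
    for (int i = 0; i < h.size(); ++i) hv[i] = h[i];
    mags.col(b) = arma::square(arma::abs(arma::fft(hv)));
  }

  // odd-reflection padded copy
  arma::mat Xp(np, nc);
  Xp.rows(pad, pad + n - 1) = X;
  for (int i = 0; i < pad; ++i) {
    Xp.row(pad - 1 - i) = 2.0 * X.row(0) - X.row(i + 1);
    Xp.row(pad + n + i) = 2.0 * X.row(n - 1) - X.row(n - 2 - i);
  }

  const int npk = (nc + 1) / 2;
  std::vector<arma::mat> res(nb, arma::mat(n, nc));
  const int block = 256;  // packed columns per FFT batch
  for (int j0 = 0; j0 < npk; j0 += block) {
    const int jn = std::min(j0 + block, npk) - j0;
    arma::cx_mat Zc(nfft, jn, arma::fill::zeros);
    for (int j = 0; j < jn; ++j) {
      const int j1 = 2 * (j0 + j), j2 = j1 + 1;
      if (j2 < nc)
        Zc.col(j).head(np) = arma::cx_vec(Xp.col(j1), Xp.col(j2));
      else
        Zc.col(j).head(np) =
          arma::cx_vec(Xp.col(j1), arma::vec(np, arma::fill::zeros));
    }
    arma::cx_mat Zf = arma::fft(Zc);
    for (int b = 0; b < nb; ++b) {
      arma::cx_mat Y = arma::ifft(arma::cx_mat(Zf.each_col() %
                                               arma::cx_vec(mags.col(b),
                                                 arma::vec(nfft, arma::fill::zeros))));
      for (int j = 0; j < jn; ++j) {
        const int j1 = 2 * (j0 + j), j2 = j1 + 1;
        res[b].col(j1) = arma::real(Y.col(j).subvec(pad, pad + n - 1));
        if (j2 < nc)
          res[b].col(j2) = arma::imag(Y.col(j).subvec(pad, pad + n - 1));
      }
    }
  }
  List out(nb);
  for (int b = 0; b < nb; ++b) out[b] = res[b];
  return out;
}
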