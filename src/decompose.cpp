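// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Band decomposition of an epoch tensor (epoch x channel x sample array):
// zero-phase FIR filtering of the EEG channels with one kernel per band,
// sharing forward FFTs between kernels of equal padded length.  Non-EEG
// channels (the derived ECG) are copied through bit-identically.
//
// Equivalent to forward-backward filtering (response |H|^2) with
// odd-reflection padding; wrap-around stays inside the discarded pads
// because nfft >= padded length and pad >= kernel length - 1.
// [[Rcpp::export]]
List decompose_bands_cpp(NumericVector arr, IntegerVector eeg_ix,
                         List kernels) {
  IntegerVector dims = arr.attr("dim");
  const int E = dims[0], C = dims[1], S = dims[2], nb = kernels.size();
  const int nch = eeg_ix.size();
  const long ncol = (long)E * nch;

  // output arrays start as copies of the input
  List out(nb);
  std::vector<double*> optr(nb);
  for (int b = 0; b < nb; ++b) {
    NumericVector a = clone(arr);
    out[b] = a;
    optr[b] = REAL(a);
  }
  const double* in = REAL(arr);

  // group kernels by padded length
  std::vector<int> klen(nb);
  for (int b = 0; b < nb; ++b)
    klen[b] = (int)as<NumericVector>(kernels[b]).size();

  std::vector<bool> done(nb, false);
  for (int b0 = 0; b0 < nb; ++b0) {
    if (done[b0]) continue;
    const int p = std::min(std::max(klen[b0], 2), S - 1);
    std::vector<int> grp;
    for (int b = b0; b < nb; ++b)
      if (!done[b] && std::min(std::max(klen[b], 2), S - 1) == p) {
        grp.push_back(b);
        done[b] = true;
      }
    const int pad = p, np = S + 2 * pad;
    int nfft = 1;
    while (nfft < np) nfft <<= 1;
    arma::mat mags(nfft, grp.size());
    for (size_t g = 0; g < grp.size(); ++g) {
      NumericVector h = kernels[grp[g]];
      arma::cx_vec hv(nfft, arma::fill::zeros);
      for (int i = 0; i < h.size(); ++i) hv[i] = h[i];
      mags.col(g) = arma::square(arma::abs(arma::fft(hv)));
    }
    const int block = 128;  // packed columns per FFT batch
    // series index c -> (epoch, channel) offset in the R array
    std::vector<long> base(ncol);
    for (long c = 0; c < ncol; ++c)
      base[c] = (long)(c % E) + (long)E * (eeg_ix[c / E] - 1);
    const long stride = (long)E * C;
    for (long j0 = 0; j0 < ncol; j0 += 2 * block) {
      const int jn = (int)std::min((long)block, (ncol - j0 + 1) / 2);
      arma::cx_mat Zc(nfft, jn, arma::fill::zeros);
      // sample-major gather: contiguous reads, block-local writes
      for (int s = 0; s < S; ++s) {
        const long off = stride * s;
        for (int j = 0; j < jn; ++j) {
          const long c1 = j0 + 2 * j, c2 = c1 + 1;
          Zc(pad + s, j) = std::complex<double>(
            in[base[c1] + off], c2 < ncol ? in[base[c2] + off] : 0.0);
        }
      }
      // odd-reflection pads
      for (int i = 0; i < pad; ++i) {
        for (int j = 0; j < jn; ++j) {
          const std::complex<double> f = Zc(pad, j), l = Zc(pad + S - 1, j);
          Zc(pad - 1 - i, j) = 2.0 * f - Zc(pad + i + 1, j);
          Zc(pad + S + i, j) = 2.0 * l - Zc(pad + S - 2 - i, j);
        }
      }
      arma::cx_mat Zf = arma::fft(Zc);
      for (size_t g = 0; g < grp.size(); ++g) {
        arma::cx_mat Y = Zf.each_col() %
          arma::cx_vec(mags.col(g), arma::vec(nfft, arma::fill::zeros));
        Y = arma::ifft(Y);
        double* o = optr[grp[g]];
        for (int s = 0; s < S; ++s) {
          const long off = stride * s;
          for (int j = 0; j < jn; ++j) {
            const long c1 = j0 + 2 * j, c2 = c1 + 1;
            const std::complex<double> y = Y(pad + s, j);
            o[base[c1] + off] = y.real();
            if (c2 < ncol) o[base[c2] + off] = y.imag();
          }
        }
      }
    }
  }
  return out;
}
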