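// im2col-based 1D convolution kernels. Activations are [N, L, C] arrays
// (batch fastest), weights are [C_in, k, C_out] flattened to a
// (k*C_in) x C_out matrix with input channel fastest within each tap,
// matching the column layout of the im2col matrix built here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
List conv1d_fwd_cpp(const arma::cube& X, const arma::mat& Wm,
                    int k, int stride, int pad) {
  const int N = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int Lout = (L + 2 * pad - k) / stride + 1;
  arma::mat Xcol(static_cast<size_t>(N) * Lout, static_cast<size_t>(k) * C);
  for (int t = 0; t < k; ++t) {
    for (int c = 0; c < C; ++c) {
      const arma::mat& Xc = X.slice(c);
      double* dst0 = Xcol.colptr(static_cast<size_t>(t) * C + c);
      for (int to = 0; to < Lout; ++to) {
        const int src = t + stride * to - pad;
        double* dst = dst0 + static_cast<size_t>(N) * to;
        if (src < 0 || src >= L)
          std::fill(dst, dst + N, 0.0);
        else
          std::memcpy(dst, Xc.colptr(src), N * sizeof(double));
      }
    }
  }
  arma::mat Y = Xcol * Wm;
  return List::create(_["Y"] = Y, _["Xcol"] = Xcol, _["Lout"] = Lout);
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::mat& dYm, const arma::mat& Xcol,
                    const arma::mat& Wm, int N, int L, int C,
                    int k, int stride, int pad, bool need_dx) {
  arma::mat dW = Xcol.t() * dYm;
  if (!need_dx)
    return List::create(_["dW"] = dW);
  arma::mat dXcol = dYm * Wm.t();
  const int Lout = dYm.n_rows / N;
  arma::cube dX(N, L, C, arma::fill::zeros);
  for (int t = 0; t < k; ++t) {
    for (int c = 0; c < C; ++c) {
      const double* src0 = dXcol.colptr(static_cast<size_t>(t) * C + c);
      arma::mat& s = dX.slice(c);
      for (int to = 0; to < Lout; ++to) {
        const int pos = t + stride * to - pad;
        if (pos < 0 || pos >= L) continue;
        const double* src = src0 + static_cast<size_t>(N) * to;
        double* dst = s.colptr(pos);
        for (int n = 0; n < N; ++n) dst[n] += src[n];
      }
    }
  }
  return List::create(_["dW"] = dW, _["dX"] = dX);
}
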