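// Single-precision convolution kernels. The one-hot inputs and the
// network's activations are exact in float; doing the im2col + GEMM in
// single precision halves the memory traffic and roughly doubles GEMM
// throughput, which dominates training time. Inputs and outputs are
// exchanged with R in double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fmat im2col_f(const arma::fmat &X, int L, int B, int k) {
  const int C = X.n_cols;
  const int P = L - k + 1;
  arma::fmat M(P * B, k * C);
  for (int c = 0; c < C; ++c) {
    const float *xcol = X.colptr(c);
    for (int j = 0; j < k; ++j) {
      float *ocol = M.colptr(c * k + j);
      for (int b = 0; b < B; ++b) {
        std::copy(xcol + (size_t)b * L + j, xcol + (size_t)b * L + j + P,
                  ocol + (size_t)b * P);
      }
    }
  }
  return M;
}

// Z = im2col(X) %*% W, all internal arithmetic in float.
// [[Rcpp::export]]
NumericMatrix cpp_conv_gemm_fwd(NumericMatrix X, NumericMatrix W,
                                int L, int B, int k) {
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(
    arma::mat(X.begin(), X.nrow(), X.ncol(), false));
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
    arma::mat(W.begin(), W.nrow(), W.ncol(), false));
  arma::fmat Z = im2col_f(Xf, L, B, k) * Wf;
  NumericMatrix out(Z.n_rows, Z.n_cols);
  std::copy(Z.begin(), Z.end(), out.begin());
  return out;
}

// Gradients of the convolution: dW = im2col(X)^T dZ and (optionally)
// dX = col2im(dZ W^T). The im2col matrix is recomputed in float rather
// than cached.
// [[Rcpp::export]]
List cpp_conv_gemm_bwd(NumericMatrix X, NumericMatrix W, NumericMatrix dZ,
                       int L, int B, int k, bool want_dx) {
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(
    arma::mat(X.begin(), X.nrow(), X.ncol(), false));
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
    arma::mat(W.begin(), W.nrow(), W.ncol(), false));
  arma::fmat dZf = arma::conv_to<arma::fmat>::from(
    arma::mat(dZ.begin(), dZ.nrow(), dZ.ncol(), false));
  arma::fmat M = im2col_f(Xf, L, B, k);
  arma::fmat dW = M.t() * dZf;
  NumericMatrix dWr(dW.n_rows, dW.n_cols);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  if (!want_dx) return List::create(_["dW"] = dWr);
  arma::fmat dM = dZf * Wf.t();
  const int C = X.ncol();
  const int P = L - k + 1;
  arma::fmat dX(L * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float *ocol = dX.colptr(c);
    for (int j = 0; j < k; ++j) {
      const float *dcol = dM.colptr(c * k + j);
      for (int b = 0; b < B; ++b) {
        const float *src = dcol + (size_t)b * P;
        float *dst = ocol + (size_t)b * L + j;
        for (int p = 0; p < P; ++p) dst[p] += src[p];
      }
    }
  }
  NumericMatrix dXr(dX.n_rows, dX.n_cols);
  std::copy(dX.begin(), dX.end(), dXr.begin());
  return List::create(_["dW"] = dWr, _["dX"] = dXr);
}
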