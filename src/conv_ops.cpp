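#include <Rcpp.h>
using namespace Rcpp;

// One-dimensional im2col for a batch of sequences.
//
// The activation of a conv layer over a batch of B sequences of length L with
// C channels is stored as an (L*B) x C matrix whose row index is l + (b-1)*L.
// im2col unrolls every valid window of width k into a row of a
// (P*B) x (k*C) matrix (P = L-k+1, row index p + (b-1)*P) so that the
// convolution becomes a single GEMM with a (k*C) x F weight matrix.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericMatrix X, int L, int B, int k) {
  const int C = X.ncol();
  const int P = L - k + 1;
  if (P < 1) stop("kernel wider than input length");
  if (X.nrow() != L * B) stop("input rows do not match L * B");
  NumericMatrix out(P * B, k * C);
  const double *x = X.begin();
  double *o = out.begin();
  const R_xlen_t PB = (R_xlen_t)P * B, LB = (R_xlen_t)L * B;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      double *ocol = o + ((R_xlen_t)(c * k + j)) * PB;
      const double *xcol = x + (R_xlen_t)c * LB;
      for (int b = 0; b < B; ++b) {
        const double *src = xcol + (R_xlen_t)b * L + j;
        double *dst = ocol + (R_xlen_t)b * P;
        std::copy(src, src + P, dst);
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add the gradient of the unrolled matrix
// back onto the (L*B) x C input layout.

// [[Rcpp::export]]
NumericMatrix cpp_col2im(NumericMatrix dM, int L, int B, int k) {
  const int P = L - k + 1;
  if (P < 1) stop("kernel wider than input length");
  const int kC = dM.ncol();
  if (kC % k != 0) stop("column count not a multiple of k");
  const int C = kC / k;
  if (dM.nrow() != (R_xlen_t)P * B) stop("gradient rows do not match P * B");
  NumericMatrix out(L * B, C);
  const double *d = dM.begin();
  double *o = out.begin();
  const R_xlen_t PB = (R_xlen_t)P * B, LB = (R_xlen_t)L * B;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      const double *dcol = d + ((R_xlen_t)(c * k + j)) * PB;
      double *ocol = o + (R_xlen_t)c * LB;
      for (int b = 0; b < B; ++b) {
        const double *src = dcol + (R_xlen_t)b * P;
        double *dst = ocol + (R_xlen_t)b * L + j;
        for (int p = 0; p < P; ++p) dst[p] += src[p];
      }
    }
  }
  return out;
}

// Fused batch-normalisation + ReLU forward pass (training mode).
// Returns the post-ReLU activation Y, the normalised pre-activation Zhat,
// and per-column batch statistics.

// [[Rcpp::export]]
List cpp_bnrelu_fwd(NumericMatrix Z, NumericVector gamma, NumericVector beta) {
  const R_xlen_t n = Z.nrow();
  const int F = Z.ncol();
  NumericMatrix Y(n, F), Zhat(n, F);
  NumericVector mu(F), var(F), invstd(F);
  for (int f = 0; f < F; ++f) {
    const double *z = &Z(0, f);
    double s = 0;
    for (R_xlen_t i = 0; i < n; ++i) s += z[i];
    const double m = s / n;
    double v = 0;
    for (R_xlen_t i = 0; i < n; ++i) { const double d = z[i] - m; v += d * d; }
    v /= n;
    const double is = 1.0 / std::sqrt(v + 1e-5);
    const double g = gamma[f], b = beta[f];
    double *zh = &Zhat(0, f), *y = &Y(0, f);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double h = (z[i] - m) * is;
      zh[i] = h;
      const double out = g * h + b;
      y[i] = out > 0 ? out : 0.0;
    }
    mu[f] = m; var[f] = v; invstd[f] = is;
  }
  return List::create(_["Y"] = Y, _["Zhat"] = Zhat, _["mu"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// Fused ReLU + batch-normalisation backward pass (training mode).
// dY is the gradient at the ReLU output; Y the cached post-ReLU activation.

// [[Rcpp::export]]
List cpp_bnrelu_bwd(NumericMatrix dY, NumericMatrix Y, NumericMatrix Zhat,
                    NumericVector invstd, NumericVector gamma) {
  const R_xlen_t n = dY.nrow();
  const int F = dY.ncol();
  NumericMatrix dZ(n, F);
  NumericVector dgamma(F), dbeta(F);
  for (int f = 0; f < F; ++f) {
    const double *dy = &dY(0, f), *y = &Y(0, f), *zh = &Zhat(0, f);
    double s1 = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double d = y[i] > 0 ? dy[i] : 0.0;
      s1 += d;
      s2 += d * zh[i];
    }
    dgamma[f] = s2; dbeta[f] = s1;
    const double m1 = s1 / n, m2 = s2 / n;
    const double g = gamma[f] * invstd[f];
    double *dz = &dZ(0, f);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double d = y[i] > 0 ? dy[i] : 0.0;
      dz[i] = g * (d - m1 - zh[i] * m2);
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Batch-normalisation + ReLU in inference mode (running statistics).

// [[Rcpp::export]]
NumericMatrix cpp_bnrelu_infer(NumericMatrix Z, NumericVector gamma,
                               NumericVector beta, NumericVector rmean,
                               NumericVector rvar) {
  const R_xlen_t n = Z.nrow();
  const int F = Z.ncol();
  NumericMatrix Y(n, F);
  for (int f = 0; f < F; ++f) {
    const double sc = gamma[f] / std::sqrt(rvar[f] + 1e-5);
    const double sh = beta[f] - rmean[f] * sc;
    const double *z = &Z(0, f);
    double *y = &Y(0, f);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double out = z[i] * sc + sh;
      y[i] = out > 0 ? out : 0.0;
    }
  }
  return Y;
}

// Max pooling over non-overlapping blocks of `pool` consecutive positions.
// A has rows p + (b-1)*P; the output has rows q + (b-1)*Q with
// Q = floor(P/pool). Returns the pooled matrix and 1-based argmax rows.

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericMatrix A, int P, int B, int pool) {
  const int F = A.ncol();
  const int Q = P / pool;
  NumericMatrix Y((R_xlen_t)Q * B, F);
  IntegerMatrix arg((R_xlen_t)Q * B, F);
  for (int f = 0; f < F; ++f) {
    const double *a = &A(0, f);
    double *y = &Y(0, f);
    int *g = &arg(0, f);
    for (int b = 0; b < B; ++b) {
      const R_xlen_t abase = (R_xlen_t)b * P;
      const R_xlen_t ybase = (R_xlen_t)b * Q;
      for (int q = 0; q < Q; ++q) {
        R_xlen_t best = abase + (R_xlen_t)q * pool;
        double bv = a[best];
        for (int j = 1; j < pool; ++j) {
          const R_xlen_t idx = abase + (R_xlen_t)q * pool + j;
          if (a[idx] > bv) { bv = a[idx]; best = idx; }
        }
        y[ybase + q] = bv;
        g[ybase + q] = (int)(best + 1);
      }
    }
  }
  return List::create(_["Y"] = Y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(NumericMatrix dQmat, IntegerMatrix arg,
                              int PB) {
  const int F = dQmat.ncol();
  NumericMatrix dA(PB, F);
  for (int f = 0; f < F; ++f) {
    const double *d = &dQmat(0, f);
    const int *g = &arg(0, f);
    double *o = &dA(0, f);
    const R_xlen_t n = dQmat.nrow();
    for (R_xlen_t i = 0; i < n; ++i) o[g[i] - 1] += d[i];
  }
  return dA;
}
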