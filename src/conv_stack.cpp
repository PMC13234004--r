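// The full convolutional stack (conv -> batch-norm -> ReLU -> max-pool,
// repeated) evaluated as one single-precision chain. Only the stack input
// and the pooled output of the last block cross the R boundary (in
// double); intermediates stay in float, which halves memory traffic and
// doubles GEMM throughput. The forward pass stashes its caches in a
// translation-unit-static store consumed by the immediately following
// backward pass (training is strictly forward-then-backward per batch).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct LayerCache {
  arma::fmat M;        // im2col of the layer input
  arma::fmat Zhat;     // normalised pre-activation (training mode)
  arma::fmat Y;        // post-ReLU, pre-pool activation
  arma::Mat<int> argmax;
  arma::frowvec invstd;
  arma::frowvec scale; // inference-mode bn scale
  int L_in, P, Q, pool, kernel, C_in;
};

std::vector<LayerCache> g_cache;
bool g_cache_train = false;

arma::fmat im2col_f(const arma::fmat &X, int L, int B, int k) {
  const int C = X.n_cols;
  const int P = L - k + 1;
  arma::fmat M(P * B, k * C);
  for (int c = 0; c < C; ++c) {
    const float *xcol = X.colptr(c);
    for (int j = 0; j < k; ++j) {
      float *ocol = M.colptr(c * k + j);
      for (int b = 0; b < B; ++b)
        std::copy(xcol + (size_t)b * L + j,
                  xcol + (size_t)b * L + j + P, ocol + (size_t)b * P);
    }
  }
  return M;
}

arma::fmat col2im_f(const arma::fmat &dM, int L, int B, int k, int C) {
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
  return dX;
}

arma::fmat as_f(const NumericMatrix &x) {
  arma::fmat out(x.nrow(), x.ncol());
  std::copy(x.begin(), x.end(), out.begin());
  return out;
}

NumericMatrix as_d(const arma::fmat &x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  std::copy(x.begin(), x.end(), out.begin());
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_conv_stack_fwd(NumericMatrix X, List Ws, List gammas, List betas,
                        List rmeans, List rvars, IntegerVector kernels,
                        IntegerVector pools, int B, bool train,
                        bool keep_cache) {
  const int nl = Ws.size();
  if (keep_cache) {
    g_cache.assign(nl, LayerCache());
    g_cache_train = train;
  }
  arma::fmat A = as_f(X);
  int L = X.nrow() / B;
  List mus(nl), vars(nl);
  for (int i = 0; i < nl; ++i) {
    const int k = kernels[i];
    const int P = L - k + 1;
    const int pool = pools[i];
    const int Q = P / pool;
    arma::fmat W = as_f(as<NumericMatrix>(Ws[i]));
    const int F = W.n_cols;
    arma::fmat M = im2col_f(A, L, B, k);
    arma::fmat Z = M * W;
    NumericVector gamma = gammas[i], beta = betas[i];
    arma::fmat Y(Z.n_rows, F);
    arma::frowvec invstd(F), scale(F);
    NumericVector mu(F), var(F);
    const size_t n = Z.n_rows;
    if (train) {
      for (int f = 0; f < F; ++f) {
        const float *z = Z.colptr(f);
        double s = 0;
        for (size_t r = 0; r < n; ++r) s += z[r];
        const double m = s / n;
        double v = 0;
        for (size_t r = 0; r < n; ++r) { const double d = z[r] - m; v += d * d; }
        v /= n;
        const float is = (float)(1.0 / std::sqrt(v + 1e-5));
        const float g = (float)gamma[f], b = (float)beta[f];
        float *zc = Z.colptr(f), *yc = Y.colptr(f);
        for (size_t r = 0; r < n; ++r) {
          const float h = (zc[r] - (float)m) * is;
          zc[r] = h;                         // Z becomes Zhat in place
          const float out = g * h + b;
          yc[r] = out > 0 ? out : 0.0f;
        }
        invstd[f] = is; mu[f] = m; var[f] = v;
      }
    } else {
      NumericVector rm = rmeans[i], rv = rvars[i];
      for (int f = 0; f < F; ++f) {
        const float sc = (float)(gamma[f] / std::sqrt(rv[f] + 1e-5));
        const float sh = (float)(beta[f] - rm[f] * (gamma[f] /
                                 std::sqrt(rv[f] + 1e-5)));
        const float *z = Z.colptr(f);
        float *yc = Y.colptr(f);
        for (size_t r = 0; r < n; ++r) {
          const float out = z[r] * sc + sh;
          yc[r] = out > 0 ? out : 0.0f;
        }
        scale[f] = sc;
      }
    }
    // max pool
    arma::fmat Ap(Q * B, F);
    arma::Mat<int> arg(Q * B, F);
    for (int f = 0; f < F; ++f) {
      const float *a = Y.colptr(f);
      float *o = Ap.colptr(f);
      int *g = arg.colptr(f);
      for (int b = 0; b < B; ++b) {
        for (int q = 0; q < Q; ++q) {
          size_t best = (size_t)b * P + (size_t)q * pool;
          float bv = a[best];
          for (int j = 1; j < pool; ++j) {
            const size_t idx = (size_t)b * P + (size_t)q * pool + j;
            if (a[idx] > bv) { bv = a[idx]; best = idx; }
          }
          o[(size_t)b * Q + q] = bv;
          g[(size_t)b * Q + q] = (int)best;
        }
      }
    }
    if (keep_cache) {
      LayerCache &cc = g_cache[i];
      cc.M = std::move(M);
      if (train) cc.Zhat = Z; else cc.scale = scale;
      cc.Y = std::move(Y);
      cc.argmax = std::move(arg);
      cc.invstd = invstd;
      cc.L_in = L; cc.P = P; cc.Q = Q; cc.pool = pool; cc.kernel = k;
      cc.C_in = A.n_cols;
    }
    mus[i] = mu; vars[i] = var;
    A = std::move(Ap);
    L = Q;
  }
  return List::create(_["H"] = as_d(A), _["mu"] = mus, _["var"] = vars);
}

// [[Rcpp::export]]
List cpp_conv_stack_bwd(NumericMatrix dH, List Ws, List gammas, int B,
                        bool want_input_grad) {
  const int nl = Ws.size();
  if ((int)g_cache.size() != nl) stop("no forward cache available");
  arma::fmat dA = as_f(dH);
  List dWs(nl), dgs(nl), dbs(nl);
  for (int i = nl - 1; i >= 0; --i) {
    LayerCache &cc = g_cache[i];
    arma::fmat W = as_f(as<NumericMatrix>(Ws[i]));
    const int F = W.n_cols;
    NumericVector gamma = gammas[i];
    // pool backward
    arma::fmat dY((size_t)cc.P * B, F, arma::fill::zeros);
    for (int f = 0; f < F; ++f) {
      const float *d = dA.colptr(f);
      const int *g = cc.argmax.colptr(f);
      float *o = dY.colptr(f);
      const size_t nq = (size_t)cc.Q * B;
      for (size_t r = 0; r < nq; ++r) o[g[r]] += d[r];
    }
    // bn + relu backward
    arma::fmat dZ(dY.n_rows, F);
    NumericVector dgamma(F), dbeta(F);
    const size_t n = dY.n_rows;
    if (g_cache_train) {
      for (int f = 0; f < F; ++f) {
        const float *dy = dY.colptr(f), *y = cc.Y.colptr(f),
          *zh = cc.Zhat.colptr(f);
        double s1 = 0, s2 = 0;
        for (size_t r = 0; r < n; ++r) {
          const float d = y[r] > 0 ? dy[r] : 0.0f;
          s1 += d; s2 += (double)d * zh[r];
        }
        dgamma[f] = s2; dbeta[f] = s1;
        const float m1 = (float)(s1 / n), m2 = (float)(s2 / n);
        const float g = (float)(gamma[f]) * cc.invstd[f];
        float *dz = dZ.colptr(f);
        for (size_t r = 0; r < n; ++r) {
          const float d = y[r] > 0 ? dy[r] : 0.0f;
          dz[r] = g * (d - m1 - zh[r] * m2);
        }
      }
    } else {
      for (int f = 0; f < F; ++f) {
        const float *dy = dY.colptr(f), *y = cc.Y.colptr(f);
        const float sc = cc.scale[f];
        float *dz = dZ.colptr(f);
        for (size_t r = 0; r < n; ++r)
          dz[r] = y[r] > 0 ? dy[r] * sc : 0.0f;
      }
    }
    arma::fmat dW = cc.M.t() * dZ;
    dWs[i] = as_d(dW);
    dgs[i] = dgamma;
    dbs[i] = dbeta;
    if (i > 0 || want_input_grad) {
      arma::fmat dM = dZ * W.t();
      dA = col2im_f(dM, cc.L_in, B, cc.kernel, cc.C_in);
    }
  }
  List out = List::create(_["dW"] = dWs, _["dgamma"] = dgs,
                          _["dbeta"] = dbs);
  if (want_input_grad) out["dX"] = as_d(dA);
  return out;
}
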