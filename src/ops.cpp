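// Memory-bound kernels of the ECA network: im2col convolution
// gather/scatter, non-overlapping max pooling, and fused
// batch-normalization + ReLU.  Matrix products go through Armadillo
// (BLAS) on non-owning memory views; every output that is fully
// overwritten is allocated uninitialized to avoid a redundant zeroing
// pass.
//
// Activation matrices have shape (B*H*W, C); index matrices hold
// 1-based row indices into the activation extended by one virtual zero
// row (value n_in + 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat view(NumericMatrix m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

// [[Rcpp::export]]
List cpp_conv_fwd(NumericMatrix X, IntegerMatrix idx, NumericMatrix W,
                  NumericVector bias) {
  const int R2 = idx.nrow(), K = idx.ncol(), C = X.ncol(), n = X.nrow();
  NumericMatrix Xcol = no_init(R2, K * C);
  for (int c = 0; c < C; ++c) {
    const double* src = &X(0, c);
    for (int k = 0; k < K; ++k) {
      double* dst = &Xcol(0, c * K + k);
      const int* id = &idx(0, k);
      for (int r = 0; r < R2; ++r) {
        const int i = id[r] - 1;
        dst[r] = (i < n) ? src[i] : 0.0;
      }
    }
  }
  NumericMatrix Y = no_init(R2, W.ncol());
  arma::mat Yv = view(Y);
  Yv = view(Xcol) * view(W);
  for (int c = 0; c < W.ncol(); ++c) {
    double* y = &Y(0, c);
    const double b = bias[c];
    for (int r = 0; r < R2; ++r) y[r] += b;
  }
  return List::create(_["Y"] = Y, _["Xcol"] = Xcol);
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericMatrix dY, NumericMatrix Xcol, IntegerMatrix idx,
                  NumericMatrix W, int n_in) {
  const int R2 = idx.nrow(), K = idx.ncol();
  const int C = W.nrow() / K, Cout = W.ncol();
  NumericMatrix dW = no_init(W.nrow(), Cout);
  arma::mat dWv = view(dW);
  dWv = view(Xcol).t() * view(dY);
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    const double* d = &dY(0, c);
    double s = 0.0;
    for (int r = 0; r < R2; ++r) s += d[r];
    db[c] = s;
  }
  arma::mat dM = view(dY) * view(W).t();        // (R2, K*C)
  NumericMatrix dX(n_in, C);                    // scatter target: zeros
  for (int c = 0; c < C; ++c) {
    double* dst = &dX(0, c);
    for (int k = 0; k < K; ++k) {
      const double* src = dM.colptr(c * K + k);
      const int* id = &idx(0, k);
      for (int r = 0; r < R2; ++r) {
        const int i = id[r] - 1;
        if (i < n_in) dst[i] += src[r];
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_pool_fwd(NumericMatrix X, IntegerMatrix idx) {
  const int R2 = idx.nrow(), K = idx.ncol(), C = X.ncol();
  NumericMatrix Y = no_init(R2, C);
  IntegerMatrix arg = no_init(R2, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &X(0, c);
    double* y = &Y(0, c);
    int* a = &arg(0, c);
    for (int r = 0; r < R2; ++r) {
      double best = src[idx(r, 0) - 1];
      int am = 1;
      for (int k = 1; k < K; ++k) {
        const double v = src[idx(r, k) - 1];
        if (v > best) { best = v; am = k + 1; }
      }
      y[r] = best;
      a[r] = am;
    }
  }
  return List::create(_["Y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_bwd(NumericMatrix dY, IntegerMatrix arg,
                           IntegerMatrix idx, int n_in) {
  const int R2 = idx.nrow(), C = dY.ncol();
  NumericMatrix dX(n_in, C);                    // scatter target: zeros
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const int* a = &arg(0, c);
    double* dst = &dX(0, c);
    for (int r = 0; r < R2; ++r)
      dst[idx(r, a[r] - 1) - 1] += dy[r];
  }
  return dX;
}

// Fused batch normalization + ReLU.  Returns the rectified activation
// A, the batch means (needed to re-center in the backward pass against
// the cached pre-BN activations), the inverse standard deviations, and
// updated running statistics.  Batch moments are accumulated in one
// pass (sum and sum of squares; activations are O(1) so the
// cancellation error is negligible).
// [[Rcpp::export]]
List cpp_bnrelu_fwd(NumericMatrix X, NumericVector gamma,
                    NumericVector beta, NumericVector rmean,
                    NumericVector rvar, bool train, double momentum,
                    double eps) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix A = no_init(n, C);
  NumericVector inv_sd = no_init(C), bmean = no_init(C);
  NumericVector new_mean(clone(rmean)), new_var(clone(rvar));
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double mu, v;
    if (train) {
      double s = 0.0, s2 = 0.0;
      for (int r = 0; r < n; ++r) {
        s += x[r];
        s2 += x[r] * x[r];
      }
      mu = s / n;
      v = s2 / n - mu * mu;
      if (v < 0.0) v = 0.0;
      new_mean[c] = (1.0 - momentum) * rmean[c] + momentum * mu;
      new_var[c] = (1.0 - momentum) * rvar[c] + momentum * v;
    } else {
      mu = rmean[c];
      v = rvar[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    inv_sd[c] = is;
    bmean[c] = mu;
    const double a = gamma[c] * is, b = beta[c] - a * mu;
    double* o = &A(0, c);
    for (int r = 0; r < n; ++r) {
      const double y = a * x[r] + b;
      o[r] = y > 0.0 ? y : 0.0;
    }
  }
  return List::create(_["A"] = A, _["bmean"] = bmean,
                      _["inv_sd"] = inv_sd, _["mean"] = new_mean,
                      _["var"] = new_var);
}

// Backward through ReLU (mask from A > 0) and batch normalization.
// X is the cached pre-BN activation; the batch mean re-centers it.
// [[Rcpp::export]]
List cpp_bnrelu_bwd(NumericMatrix dA, NumericMatrix A, NumericMatrix X,
                    NumericVector bmean, NumericVector inv_sd,
                    NumericVector gamma) {
  const int n = dA.nrow(), C = dA.ncol();
  NumericMatrix dX = no_init(n, C);
  NumericVector dgamma = no_init(C), dbeta = no_init(C);
  for (int c = 0; c < C; ++c) {
    const double* da = &dA(0, c);
    const double* aa = &A(0, c);
    const double* x = &X(0, c);
    const double is = inv_sd[c], mu = bmean[c];
    double sb = 0.0, sg = 0.0;
    for (int r = 0; r < n; ++r) {
      if (aa[r] > 0.0) {
        sb += da[r];
        sg += da[r] * (x[r] - mu) * is;
      }
    }
    dbeta[c] = sb;
    dgamma[c] = sg;
    const double a = gamma[c] * is, mb = sb / n, mg = sg / n;
    double* dx = &dX(0, c);
    for (int r = 0; r < n; ++r) {
      const double dy = aa[r] > 0.0 ? da[r] : 0.0;
      dx[r] = a * (dy - mb - (x[r] - mu) * is * mg);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
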