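// 1-D convolution and max-pooling kernels for the network engine.
// Sequence tensors are (nt * batch) x channels matrices, time-fastest
// within each batch element, so each (tap, batch-element) pair maps to a
// contiguous row range and "same" padding reduces to clipping the range.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col: col(:, j-block) = x shifted by tap j (zero outside each
// batch element), built with per-column contiguous copies.
static arma::mat im2col(const arma::mat& x, int nt, int batch, int k,
                        int left) {
  const int C = x.n_cols, M = nt * batch;
  arma::mat col(M, C * k, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int d = j - left;
    const int t0 = std::max(0, -d), t1 = std::min(nt, nt - d);
    if (t1 <= t0) continue;
    const int len = t1 - t0;
    for (int c = 0; c < C; ++c) {
      const double* src = x.colptr(c);
      double* dst = col.colptr(j * C + c);
      for (int b = 0; b < batch; ++b)
        std::memcpy(dst + b * nt + t0, src + b * nt + t0 + d,
                    len * sizeof(double));
    }
  }
  return col;
}

// x: (nt*batch) x C;  W: (C*k) x cout, rows of block j = tap j;
// out(t) = sum_j x(t + j - 1 - left) * W_j  (zero outside [1, nt])
// [[Rcpp::export(name = ".convFwdC")]]
arma::mat convFwdC(const arma::mat& x, const arma::mat& W, int nt,
                   int batch, int k, int left) {
  return im2col(x, nt, batch, k, left) * W;
}

// [[Rcpp::export(name = ".convBwdC")]]
List convBwdC(const arma::mat& x, const arma::mat& W, const arma::mat& dout,
              int nt, int batch, int k, int left) {
  const int C = x.n_cols;
  arma::mat col = im2col(x, nt, batch, k, left);
  arma::mat dW = col.t() * dout;
  arma::mat dcol = dout * W.t();
  // col2im scatter-add
  arma::mat dx(x.n_rows, C, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int d = j - left;
    const int t0 = std::max(0, -d), t1 = std::min(nt, nt - d);
    if (t1 <= t0) continue;
    for (int c = 0; c < C; ++c) {
      const double* src = dcol.colptr(j * C + c);
      double* dst = dx.colptr(c);
      for (int b = 0; b < batch; ++b) {
        const double* s = src + b * nt + t0;
        double* t = dst + b * nt + t0 + d;
        for (int i = 0; i < t1 - t0; ++i) t[i] += s[i];
      }
    }
  }
  return List::create(Named("dW") = dW, Named("dx") = dx);
}

// rectifier activations: alpha = 0 gives ReLU, > 0 leaky ReLU
// [[Rcpp::export(name = ".reluFwdC")]]
NumericMatrix reluFwdC(const NumericMatrix& x, double alpha) {
  const R_xlen_t n = x.size();
  NumericMatrix out(x.nrow(), x.ncol());
  const double* px = x.begin(); double* po = out.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    po[i] = px[i] > 0 ? px[i] : alpha * px[i];
  return out;
}

// [[Rcpp::export(name = ".reluBwdC")]]
NumericMatrix reluBwdC(const NumericMatrix& x, const NumericMatrix& dout,
                       double alpha) {
  const R_xlen_t n = x.size();
  NumericMatrix dx(x.nrow(), x.ncol());
  const double* px = x.begin(); const double* pd = dout.begin();
  double* po = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    po[i] = px[i] > 0 ? pd[i] : alpha * pd[i];
  return dx;
}

// max pool, window k, stride 1, same padding; ties -> earliest tap
// [[Rcpp::export(name = ".poolFwdC")]]
List poolFwdC(const NumericMatrix& x, int nt, int batch, int k, int left) {
  const int C = x.ncol();
  NumericMatrix out(x.nrow(), C);
  IntegerMatrix arg(x.nrow(), C);
  for (int c = 0; c < C; ++c) {
    const double* px = &x(0, c);
    double* po = &out(0, c);
    int* pa = &arg(0, c);
    for (int b = 0; b < batch; ++b) {
      const double* xb = px + b * nt;
      double* ob = po + b * nt;
      int* ab = pa + b * nt;
      for (int t = 0; t < nt; ++t) {
        const int j0 = std::max(0, left - t);
        const int j1 = std::min(k, nt + left - t);
        double best = xb[t + j0 - left];
        int bestj = j0;
        for (int j = j0 + 1; j < j1; ++j) {
          const double v = xb[t + j - left];
          if (v > best) { best = v; bestj = j; }
        }
        ob[t] = best;
        ab[t] = bestj;
      }
    }
  }
  return List::create(Named("out") = out, Named("arg") = arg);
}

// [[Rcpp::export(name = ".poolBwdC")]]
NumericMatrix poolBwdC(const IntegerMatrix& arg, const NumericMatrix& dout,
                       int nt, int batch, int k, int left) {
  const int C = dout.ncol();
  NumericMatrix dx(dout.nrow(), C);
  for (int c = 0; c < C; ++c) {
    const double* pd = &dout(0, c);
    const int* pa = &arg(0, c);
    double* px = &dx(0, c);
    for (int b = 0; b < batch; ++b)
      for (int t = 0; t < nt; ++t) {
        const int i = b * nt + t;
        px[i + pa[i] - left] += pd[i];
      }
  }
  return dx;
}

// column-broadcast helpers for batch normalization (one pass, no
// temporary full-size matrices on the R side)

// out = (x - mu) * s  per column
// [[Rcpp::export(name = ".colCenterScaleC")]]
NumericMatrix colCenterScaleC(const NumericMatrix& x,
                              const NumericVector& mu,
                              const NumericVector& s) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], sc = s[c];
    for (int i = 0; i < n; ++i) out(i, c) = (x(i, c) - m) * sc;
  }
  return out;
}

// out = x * s + t  per column
// [[Rcpp::export(name = ".colScaleShiftC")]]
NumericMatrix colScaleShiftC(const NumericMatrix& x,
                             const NumericVector& s,
                             const NumericVector& t) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double sc = s[c], tc = t[c];
    for (int i = 0; i < n; ++i) out(i, c) = x(i, c) * sc + tc;
  }
  return out;
}

// training-mode batch-norm backward: given dout, xhat, gamma, invstd,
// returns dx and accumulates dgamma/dbeta; dx = (gamma * invstd / n) *
// (n * dxhat - sum(dxhat) - xhat * sum(dxhat * xhat)), dxhat = dout * gamma
// [[Rcpp::export(name = ".bnBwdTrainC")]]
List bnBwdTrainC(const NumericMatrix& dout, const NumericMatrix& xhat,
                 const NumericVector& gamma, const NumericVector& invstd) {
  const int n = dout.nrow(), C = dout.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0, db = 0, dg = 0;
    for (int i = 0; i < n; ++i) {
      const double dh = dout(i, c) * gamma[c];
      s1 += dh; s2 += dh * xhat(i, c);
      db += dout(i, c); dg += dout(i, c) * xhat(i, c);
    }
    const double f = invstd[c] / n;
    for (int i = 0; i < n; ++i)
      dx(i, c) = f * (n * dout(i, c) * gamma[c] - s1 - xhat(i, c) * s2);
    dgamma[c] = dg; dbeta[c] = db;
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// one-pass training-mode batch-norm forward: returns out, xhat, mu, var
// [[Rcpp::export(name = ".bnFwdTrainC")]]
List bnFwdTrainC(const NumericMatrix& x, const NumericVector& gamma,
                 const NumericVector& beta, double eps) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix out(n, C), xhat(n, C);
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* px = &x(0, c);
    double s = 0;
    for (int i = 0; i < n; ++i) s += px[i];
    const double m = s / n;
    double v = 0;
    for (int i = 0; i < n; ++i) { const double d = px[i] - m; v += d * d; }
    v /= n;
    const double invstd = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], b = beta[c];
    double* ph = &xhat(0, c);
    double* po = &out(0, c);
    for (int i = 0; i < n; ++i) {
      const double h = (px[i] - m) * invstd;
      ph[i] = h;
      po[i] = h * g + b;
    }
    mu[c] = m; var[c] = v;
  }
  return List::create(Named("out") = out, Named("xhat") = xhat,
                      Named("mu") = mu, Named("var") = var);
}
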