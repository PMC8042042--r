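// Compiled kernels for the convolutional blocks.  Activation layout is
// column-major (H, W, C, N): element (h, w, c, n) sits at
// h + H*(w + W*(c + C*n)), so each (c, n) channel plane is contiguous.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Patch matrix: rows ordered (ki fastest, kj, c), columns (i fastest, j, n).
static void im2col_fill(const double* X, int H, int W, int C, int N,
                        int k, int s, int p, int oh, int ow, double* cm) {
  const size_t nrow = static_cast<size_t>(k) * k * C;
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        size_t col = i + static_cast<size_t>(oh) * (j + static_cast<size_t>(ow) * n);
        double* dst = cm + col * nrow;
        for (int c = 0; c < C; ++c) {
          const double* plane = X + (static_cast<size_t>(n) * C + c) * H * W;
          for (int kj = 0; kj < k; ++kj) {
            int ww = j * s + kj - p;
            if (ww < 0 || ww >= W) { dst += k; continue; }
            const double* colsrc = plane + static_cast<size_t>(ww) * H;
            int h0 = i * s - p;
            for (int ki = 0; ki < k; ++ki) {
              int hh = h0 + ki;
              *dst = (hh >= 0 && hh < H) ? colsrc[hh] : 0.0;
              ++dst;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
List conv_fwd_cpp(NumericVector X, IntegerVector dims, NumericMatrix Wm,
                  NumericVector b, int k, int s, int p) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int oh = out_dim(H, k, s, p), ow = out_dim(W, k, s, p);
  int cout = Wm.nrow();
  NumericMatrix CmatR(k * k * C, static_cast<R_xlen_t>(oh) * ow * N);
  im2col_fill(X.begin(), H, W, C, N, k, s, p, oh, ow, CmatR.begin());
  arma::mat Cmat(CmatR.begin(), CmatR.nrow(), CmatR.ncol(), false);
  arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  arma::mat Y = Wa * Cmat;                      // (cout, oh*ow*N)
  Y.each_col() += arma::vec(b.begin(), b.size());
  // permute to (oh, ow, cout, N)
  NumericVector out(static_cast<R_xlen_t>(oh) * ow * cout * N);
  double* o = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < cout; ++c)
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i)
          *o++ = Y(c, i + static_cast<arma::uword>(oh) * (j + static_cast<arma::uword>(ow) * n));
  out.attr("dim") = IntegerVector::create(oh, ow, cout, N);
  return List::create(_["out"] = out,
                      _["Cmat"] = CmatR,
                      _["oh"] = oh, _["ow"] = ow);
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(NumericVector dY, NumericMatrix Cmat_r, NumericMatrix Wm,
                  IntegerVector in_dims, int k, int s, int p) {
  IntegerVector od = dY.attr("dim");
  int oh = od[0], ow = od[1], cout = od[2], N = od[3];
  int H = in_dims[0], W = in_dims[1], C = in_dims[2];
  arma::mat dYmat(cout, static_cast<arma::uword>(oh) * ow * N);
  const double* g = dY.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < cout; ++c)
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i)
          dYmat(c, i + static_cast<arma::uword>(oh) * (j + static_cast<arma::uword>(ow) * n)) = *g++;
  arma::mat Cmat(Cmat_r.begin(), Cmat_r.nrow(), Cmat_r.ncol(), false);
  arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  arma::mat dW = dYmat * Cmat.t();
  arma::vec db = arma::sum(dYmat, 1);
  arma::mat dCmat = Wa.t() * dYmat;             // (k*k*C, oh*ow*N)
  NumericVector dX(static_cast<R_xlen_t>(H) * W * C * N);
  double* dx = dX.begin();
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        arma::uword col = i + static_cast<arma::uword>(oh) * (j + static_cast<arma::uword>(ow) * n);
        const double* src = dCmat.colptr(col);
        for (int c = 0; c < C; ++c) {
          double* plane = dx + (static_cast<size_t>(n) * C + c) * H * W;
          for (int kj = 0; kj < k; ++kj) {
            int ww = j * s + kj - p;
            if (ww < 0 || ww >= W) { src += k; continue; }
            double* colDst = plane + static_cast<size_t>(ww) * H;
            int h0 = i * s - p;
            for (int ki = 0; ki < k; ++ki) {
              int hh = h0 + ki;
              if (hh >= 0 && hh < H) colDst[hh] += *src;
              ++src;
            }
          }
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dA"] = dX, _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// [[Rcpp::export(name = ".pool_fwd_cpp")]]
List pool_fwd_cpp(NumericVector X, IntegerVector dims) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int H2 = H / 2, W2 = W / 2;
  R_xlen_t len = static_cast<R_xlen_t>(H2) * W2 * C * N;
  NumericVector out(len);
  IntegerVector arg(len);
  const double* x = X.begin();
  double* o = out.begin();
  int* a = arg.begin();
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double* plane = x + cn * H * W;
    for (int j = 0; j < W2; ++j) {
      const double* c0 = plane + static_cast<size_t>(2 * j) * H;
      const double* c1 = c0 + H;
      for (int i = 0; i < H2; ++i) {
        int r = 2 * i;
        double v = c0[r]; int am = 1;          // offsets: 1=(0,0) 2=(1,0) 3=(0,1) 4=(1,1)
        if (c0[r + 1] > v) { v = c0[r + 1]; am = 2; }
        if (c1[r] > v) { v = c1[r]; am = 3; }
        if (c1[r + 1] > v) { v = c1[r + 1]; am = 4; }
        *o++ = v;
        *a++ = am;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  arg.attr("dim") = IntegerVector::create(H2, W2, C, N);
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export(name = ".pool_bwd_cpp")]]
NumericVector pool_bwd_cpp(NumericVector dY, IntegerVector arg,
                           IntegerVector in_dims) {
  int H = in_dims[0], W = in_dims[1], C = in_dims[2], N = in_dims[3];
  IntegerVector od = dY.attr("dim");
  int H2 = od[0], W2 = od[1];
  NumericVector dX(static_cast<R_xlen_t>(H) * W * C * N);
  const double* g = dY.begin();
  const int* a = arg.begin();
  double* dx = dX.begin();
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    double* plane = dx + cn * H * W;
    for (int j = 0; j < W2; ++j) {
      double* c0 = plane + static_cast<size_t>(2 * j) * H;
      double* c1 = c0 + H;
      for (int i = 0; i < H2; ++i) {
        int r = 2 * i;
        switch (*a++) {
          case 1: c0[r] += *g; break;
          case 2: c0[r + 1] += *g; break;
          case 3: c1[r] += *g; break;
          default: c1[r + 1] += *g; break;
        }
        ++g;
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  return dX;
}

// Per-channel mean and biased variance over (H, W, N).
// [[Rcpp::export(name = ".bn2d_stats_cpp")]]
List bn2d_stats_cpp(NumericVector X, IntegerVector dims) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector mu(C), var(C);
  const double* x = X.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* plane = x + (static_cast<size_t>(n) * C + c) * hw;
      for (size_t t = 0; t < hw; ++t) {
        double v = plane[t];
        s += v;
        s2 += v * v;
      }
    }
    double m = static_cast<double>(hw) * N;
    mu[c] = s / m;
    double v = s2 / m - mu[c] * mu[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// Normalize + affine; returns Y and xhat (kept for the backward pass).
// [[Rcpp::export(name = ".bn2d_apply_cpp")]]
List bn2d_apply_cpp(NumericVector X, IntegerVector dims, NumericVector gamma,
                    NumericVector beta, NumericVector mu, NumericVector var,
                    double eps, bool want_xhat) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector Y(X.size());
  NumericVector xhat = want_xhat ? NumericVector(X.size()) : NumericVector(0);
  const double* x = X.begin();
  double* y = Y.begin();
  double* xh = want_xhat ? xhat.begin() : nullptr;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t off = (static_cast<size_t>(n) * C + c) * hw;
      double sd = std::sqrt(var[c] + eps);
      double g = gamma[c], b = beta[c], m = mu[c];
      for (size_t t = 0; t < hw; ++t) {
        double h = (x[off + t] - m) / sd;
        if (xh) xh[off + t] = h;
        y[off + t] = g * h + b;
      }
    }
  }
  Y.attr("dim") = dims;
  if (want_xhat) xhat.attr("dim") = dims;
  return List::create(_["out"] = Y, _["xhat"] = xhat);
}

// [[Rcpp::export(name = ".bn2d_bwd_cpp")]]
List bn2d_bwd_cpp(NumericVector dY, NumericVector xhat, IntegerVector dims,
                  NumericVector gamma, NumericVector var, double eps) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  size_t hw = static_cast<size_t>(H) * W;
  double m = static_cast<double>(hw) * N;
  NumericVector dX(dY.size()), dgamma(C), dbeta(C);
  const double* g = dY.begin();
  const double* xh = xhat.begin();
  // first pass: per-channel sums
  std::vector<double> sum_dy(C, 0.0), sum_dyxh(C, 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = (static_cast<size_t>(n) * C + c) * hw;
      double s = 0, sx = 0;
      for (size_t t = 0; t < hw; ++t) {
        s += g[off + t];
        sx += g[off + t] * xh[off + t];
      }
      sum_dy[c] += s;
      sum_dyxh[c] += sx;
    }
  for (int c = 0; c < C; ++c) {
    dgamma[c] = sum_dyxh[c];
    dbeta[c] = sum_dy[c];
  }
  double* dx = dX.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = (static_cast<size_t>(n) * C + c) * hw;
      double sd = std::sqrt(var[c] + eps);
      double gc = gamma[c] / sd;
      double mdy = sum_dy[c] / m, mdyxh = sum_dyxh[c] / m;
      for (size_t t = 0; t < hw; ++t)
        dx[off + t] = gc * (g[off + t] - mdy - xh[off + t] * mdyxh);
    }
  dX.attr("dim") = dims;
  return List::create(_["dA"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericVector relu_fwd_cpp(NumericVector X) {
  NumericVector Y(X.size());
  const double* x = X.begin();
  double* y = Y.begin();
  for (R_xlen_t t = 0; t < X.size(); ++t) y[t] = x[t] > 0 ? x[t] : 0;
  Y.attr("dim") = X.attr("dim");
  return Y;
}

// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector dY, NumericVector X) {
  NumericVector dX(dY.size());
  const double* g = dY.begin();
  const double* x = X.begin();
  double* dx = dX.begin();
  for (R_xlen_t t = 0; t < dY.size(); ++t) dx[t] = x[t] > 0 ? g[t] : 0;
  dX.attr("dim") = dY.attr("dim");
  return dX;
}
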