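// Minimal convolution / pooling kernels for the small CNN backbone.
// Layout convention: activations are (H, W, C, N) column-major R arrays,
// weights are (kh, kw, Cin, Cout). Convolutions are stride-1 with
// "same" zero padding (kh, kw odd). im2col + GEMM per image.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, arma::mat& col) {
  // col: (kh*kw*Cin) x (H*W); zero padding of (kh-1)/2, (kw-1)/2
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = (kj * kh + ki) + c * kh * kw;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pw;
          if (sj < 0 || sj >= W) continue;
          const double* src = xc + (size_t)sj * H;
          double* dst = col.colptr(0) + r; // strided writes along row r
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - ph;
            if (si < 0 || si >= H) continue;
            dst[(size_t)(j * H + i) * col.n_rows] = src[si];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int Cin,
                   int kh, int kw, double* x) {
  // adjoint of im2col: accumulate patches back into the (padded) image
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  std::fill(x, x + (size_t)H * W * Cin, 0.0);
  for (int c = 0; c < Cin; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = (kj * kh + ki) + c * kh * kw;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pw;
          if (sj < 0 || sj >= W) continue;
          double* dst = xc + (size_t)sj * H;
          const double* src = col.colptr(0) + r;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - ph;
            if (si < 0 || si >= H) continue;
            dst[si] += src[(size_t)(j * H + i) * col.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: channel mismatch");
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat col((size_t)kh * kw * Cin, (size_t)H * W);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, kh, kw, col);
    arma::mat out = col.t() * Wm;           // (H*W) x Cout
    out.each_row() += bv;
    std::copy(out.begin(), out.end(), y.begin() + (size_t)n * H * W * Cout);
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false);
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = xd;
  arma::mat dW((size_t)kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col((size_t)kh * kw * Cin, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)n * H * W * Cout,
                  (size_t)H * W, Cout, false);
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, kh, kw, col);
    dW += col * dYm;
    db += arma::sum(dYm, 0).t();
    arma::mat dcol = Wm * dYm.t();          // (kh*kw*Cin) x (H*W)
    col2im(dcol, H, W, Cin, kh, kw, dx.begin() + (size_t)n * H * W * Cin);
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(rng = false)]]
List maxpool2_forward_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size());              // 0-based index into x
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          size_t best = base + (size_t)(2 * j) * H + 2 * i;
          double bv = x[best];
          const size_t cand[3] = {base + (size_t)(2 * j) * H + 2 * i + 1,
                                  base + (size_t)(2 * j + 1) * H + 2 * i,
                                  base + (size_t)(2 * j + 1) * H + 2 * i + 1};
          for (int k = 0; k < 3; ++k)
            if (x[cand[k]] > bv) { bv = x[cand[k]]; best = cand[k]; }
          y[o] = bv;
          arg[o] = (int)best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector maxpool2_backward_cpp(NumericVector dy, IntegerVector argmax,
                                    IntegerVector dims_in) {
  NumericVector dx((size_t)dims_in[0] * dims_in[1] * dims_in[2] * dims_in[3]);
  dx.attr("dim") = dims_in;
  for (R_xlen_t k = 0; k < dy.size(); ++k) dx[argmax[k]] += dy[k];
  return dx;
}

// ---- fused conv -> batchnorm -> ReLU -> maxpool block ----
// Caches kept for backward: xhat (normalized pre-activation), inv (1/sd per
// channel), pool argmax. The ReLU mask is recomputed from xhat in backward.

// [[Rcpp::export(rng = false)]]
List block_forward_cpp(NumericVector x, NumericVector w, NumericVector b,
                       NumericVector gamma, NumericVector beta,
                       NumericVector rmean, NumericVector rvar,
                       bool training, double momentum, double eps,
                       bool keep_cache) {
  NumericVector z = conv2d_forward_cpp(x, w, b);
  IntegerVector zd = z.attr("dim");
  const int H = zd[0], W = zd[1], C = zd[2], N = zd[3];
  const size_t plane = (size_t)H * W, img = plane * C;
  std::vector<double> mu(C), var(C);
  NumericVector new_rmean = clone(rmean), new_rvar = clone(rvar);
  if (training) {
    const double m = (double)plane * N;
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = z.begin() + n * img + c * plane;
        for (size_t k = 0; k < plane; ++k) { s += p[k]; s2 += p[k] * p[k]; }
      }
      mu[c] = s / m;
      var[c] = s2 / m - mu[c] * mu[c];
      new_rmean[c] = momentum * rmean[c] + (1 - momentum) * mu[c];
      new_rvar[c] = momentum * rvar[c] + (1 - momentum) * var[c];
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = rmean[c]; var[c] = rvar[c]; }
  }
  NumericVector inv(C);
  for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(var[c] + eps);
  // in place: z <- relu(gamma * xhat + beta); keep xhat separately if needed
  NumericVector xhat;
  if (keep_cache) { xhat = NumericVector(z.size()); xhat.attr("dim") = zd; }
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* p = z.begin() + n * img + c * plane;
      double* q = keep_cache ? xhat.begin() + n * img + c * plane : nullptr;
      const double g = gamma[c], bb = beta[c], m0 = mu[c], iv = inv[c];
      for (size_t k = 0; k < plane; ++k) {
        const double xh = (p[k] - m0) * iv;
        if (keep_cache) q[k] = xh;
        const double a = g * xh + bb;
        p[k] = a > 0 ? a : 0;
      }
    }
  }
  List pool = maxpool2_forward_cpp(z);
  return List::create(_["y"] = pool["y"], _["argmax"] = pool["argmax"],
                      _["xhat"] = xhat, _["inv"] = inv,
                      _["relu_dim"] = zd,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// bn_training: use the full batch-norm backward (training mode, where the
// batch statistics depend on the inputs) or the inference-mode backward
// (batch norm is a fixed affine map; no centering terms).
// [[Rcpp::export(rng = false)]]
List block_backward_cpp(NumericVector x, NumericVector w,
                        NumericVector gamma, NumericVector beta,
                        NumericVector xhat, NumericVector inv,
                        NumericVector dy, IntegerVector argmax,
                        IntegerVector relu_dim, bool bn_training) {
  const int H = relu_dim[0], W = relu_dim[1], C = relu_dim[2], N = relu_dim[3];
  const size_t plane = (size_t)H * W, img = plane * C;
  // unpool
  NumericVector da = maxpool2_backward_cpp(dy, argmax, relu_dim);
  // relu mask from a = gamma*xhat + beta; then bn backward into da (as dz)
  NumericVector dgamma(C), dbeta(C);
  const double m = (double)plane * N;
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], bb = beta[c];
    double s1 = 0, s2 = 0, dg = 0, db = 0;
    for (int n = 0; n < N; ++n) {
      double* pd = da.begin() + n * img + c * plane;
      const double* ph = xhat.begin() + n * img + c * plane;
      for (size_t k = 0; k < plane; ++k) {
        if (g * ph[k] + bb <= 0) pd[k] = 0;    // ReLU gate
        dg += pd[k] * ph[k];
        db += pd[k];
      }
    }
    dgamma[c] = dg; dbeta[c] = db;
    s1 = db; s2 = dg;                           // sums of dxhat/gamma terms
    const double iv = inv[c];
    for (int n = 0; n < N; ++n) {
      double* pd = da.begin() + n * img + c * plane;
      const double* ph = xhat.begin() + n * img + c * plane;
      for (size_t k = 0; k < plane; ++k) {
        const double dxhat = pd[k] * g;
        pd[k] = bn_training ?
          (iv / m) * (m * dxhat - g * s1 - ph[k] * g * s2) :
          iv * dxhat;
      }
    }
  }
  da.attr("dim") = relu_dim;
  List cb = conv2d_backward_cpp(x, w, da);
  return List::create(_["dx"] = cb["dx"], _["dw"] = cb["dw"],
                      _["db"] = cb["db"], _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
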