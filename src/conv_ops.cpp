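#include <Rcpp.h>
using namespace Rcpp;

// Direct 2-D convolution kernels on channel-first tensors.
//
// Tensor layout everywhere: a (C, H, W, B) array flattened column-major, so
// the channel index moves fastest and the per-pixel channel vector is
// contiguous.  Weights: a Cout x (Cin*k*k) matrix, its columns indexed by
// (cin fastest, then kh, then kw), so each weight column is contiguous over
// Cout.  The inner loops accumulate rank-1 updates over the contiguous
// channel dimension, which the compiler vectorizes; no patch-matrix
// intermediate is materialized.

// [[Rcpp::export]]
NumericVector conv2d_direct(const NumericVector& x, const NumericMatrix& w,
                            const NumericVector& bias, int C, int H, int W,
                            int B, int k, int stride, int pad) {
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  const int Cout = w.nrow();
  NumericVector out((R_xlen_t)Cout * OH * OW * B);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* bp = bias.begin();
  double* op = out.begin();
  std::vector<double> acc(Cout);
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (size_t)b * C * H * W;
    double* ob = op + (size_t)b * Cout * OH * OW;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        for (int j = 0; j < Cout; ++j) acc[j] = bp[j];
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * stride + kw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * stride + kh - pad;
            if (ih < 0 || ih >= H) continue;
            const double* xs = xb + (size_t)C * (ih + H * iw);
            const double* wc = wp + (size_t)Cout * C * (kh + k * kw);
            for (int c = 0; c < C; ++c) {
              const double xv = xs[c];
              const double* wcol = wc + (size_t)Cout * c;
              for (int j = 0; j < Cout; ++j) acc[j] += wcol[j] * xv;
            }
          }
        }
        double* os = ob + (size_t)Cout * (oh + OH * ow);
        for (int j = 0; j < Cout; ++j) os[j] = acc[j];
      }
    }
  }
  return out;
}

// Combined backward: returns list(dx, dW, db) for the same layout.
// [[Rcpp::export]]
List conv2d_direct_bw(const NumericVector& x, const NumericMatrix& w,
                      const NumericVector& dout, int C, int H, int W, int B,
                      int k, int stride, int pad) {
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  const int Cout = w.nrow();
  NumericVector dx((R_xlen_t)C * H * W * B);
  NumericMatrix dW(Cout, C * k * k);
  NumericVector db(Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dp = dout.begin();
  double* dxp = dx.begin();
  double* dwp = dW.begin();
  double* dbp = db.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (size_t)b * C * H * W;
    double* dxb = dxp + (size_t)b * C * H * W;
    const double* dob = dp + (size_t)b * Cout * OH * OW;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* dpix = dob + (size_t)Cout * (oh + OH * ow);
        for (int j = 0; j < Cout; ++j) dbp[j] += dpix[j];
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * stride + kw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * stride + kh - pad;
            if (ih < 0 || ih >= H) continue;
            const double* xs = xb + (size_t)C * (ih + H * iw);
            double* dxs = dxb + (size_t)C * (ih + H * iw);
            const size_t koff = (size_t)Cout * C * (kh + k * kw);
            const double* wc = wp + koff;
            double* dwc = dwp + koff;
            for (int c = 0; c < C; ++c) {
              const double xv = xs[c];
              const double* wcol = wc + (size_t)Cout * c;
              double* dwcol = dwc + (size_t)Cout * c;
              double a = 0.0;
              for (int j = 0; j < Cout; ++j) {
                const double dj = dpix[j];
                a += wcol[j] * dj;
                dwcol[j] += dj * xv;
              }
              dxs[c] += a;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Integer-pixel translation with edge replication, used by the synthetic
// motion-jitter model (keeps interpolation out of the ground-truth path).
// [[Rcpp::export]]
NumericVector shift_hw(const NumericVector& img, int H, int W, int C,
                       int dy, int dx) {
  NumericVector out((R_xlen_t)H * W * C);
  const double* ip = img.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* ic = ip + (size_t)c * H * W;
    double* oc = op + (size_t)c * H * W;
    for (int w = 0; w < W; ++w) {
      int sw = w - dx; if (sw < 0) sw = 0; if (sw >= W) sw = W - 1;
      for (int h = 0; h < H; ++h) {
        int sh = h - dy; if (sh < 0) sh = 0; if (sh >= H) sh = H - 1;
        oc[h + (size_t)H * w] = ic[sh + (size_t)H * sw];
      }
    }
  }
  return out;
}

// Multiply a (C, H, W, B) tensor by a per-(channel, frame) mask without
// materializing the broadcast mask (channel-dropout apply / adjoint).
// [[Rcpp::export]]
NumericVector mul_mask_cb(const NumericVector& x, const NumericMatrix& m,
                          int C, int H, int W, int B) {
  NumericVector out((R_xlen_t)C * H * W * B);
  const double* xp = x.begin();
  const double* mp = m.begin();
  double* op = out.begin();
  const size_t hw = (size_t)H * W;
  for (int b = 0; b < B; ++b) {
    const double* mb = mp + (size_t)b * C;
    const double* xb = xp + (size_t)b * C * hw;
    double* ob = op + (size_t)b * C * hw;
    for (size_t j = 0; j < hw; ++j) {
      const double* xs = xb + j * C;
      double* os = ob + j * C;
      for (int c = 0; c < C; ++c) os[c] = xs[c] * mb[c];
    }
  }
  return out;
}

// ReLU forward and its adjoint gated by the cached output.
// [[Rcpp::export]]
NumericVector relu_fw_cpp(const NumericVector& x) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericVector relu_bw_cpp(const NumericVector& dout, const NumericVector& out) {
  NumericVector dx(dout.size());
  const double* dp = dout.begin();
  const double* op = out.begin();
  double* xp = dx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) xp[i] = op[i] > 0 ? dp[i] : 0.0;
  return dx;
}

// Fused batch-norm forward over a (C, M) view (channel fastest): returns
// the normalized output, the cached xhat, 1/sd, and the batch moments.
// [[Rcpp::export]]
List bn_fw_cpp(const NumericVector& x, int C, double M,
               const NumericVector& gamma, const NumericVector& beta,
               double eps) {
  const R_xlen_t n = x.size();
  const R_xlen_t m = (R_xlen_t)M;
  NumericVector mu(C), var(C), inv(C);
  const double* xp = x.begin();
  double* mup = mu.begin();
  for (R_xlen_t i = 0; i < n; )
    for (int c = 0; c < C; ++c, ++i) mup[c] += xp[i];
  for (int c = 0; c < C; ++c) mup[c] /= m;
  double* vp = var.begin();
  for (R_xlen_t i = 0; i < n; )
    for (int c = 0; c < C; ++c, ++i) {
      const double d = xp[i] - mup[c];
      vp[c] += d * d;
    }
  for (int c = 0; c < C; ++c) {
    vp[c] /= m;
    inv[c] = 1.0 / std::sqrt(vp[c] + eps);
  }
  NumericVector out(n), xhat(n);
  double* op = out.begin();
  double* hp = xhat.begin();
  const double* gp = gamma.begin();
  const double* bp = beta.begin();
  const double* ip = inv.begin();
  for (R_xlen_t i = 0; i < n; )
    for (int c = 0; c < C; ++c, ++i) {
      const double h = (xp[i] - mup[c]) * ip[c];
      hp[i] = h;
      op[i] = gp[c] * h + bp[c];
    }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv,
                      _["mu"] = mu, _["var"] = var);
}

// Fused batch-norm backward (training mode).
// [[Rcpp::export]]
List bn_bw_cpp(const NumericVector& dout, const NumericVector& xhat,
               const NumericVector& inv, const NumericVector& gamma,
               int C, double M, bool training) {
  const R_xlen_t n = dout.size();
  NumericVector dgamma(C), dbeta(C);
  const double* dp = dout.begin();
  const double* hp = xhat.begin();
  double* dgp = dgamma.begin();
  double* dbp = dbeta.begin();
  for (R_xlen_t i = 0; i < n; )
    for (int c = 0; c < C; ++c, ++i) {
      dgp[c] += dp[i] * hp[i];
      dbp[c] += dp[i];
    }
  NumericVector dx(n);
  double* xp = dx.begin();
  const double* gp = gamma.begin();
  const double* ip = inv.begin();
  if (training) {
    for (R_xlen_t i = 0; i < n; )
      for (int c = 0; c < C; ++c, ++i)
        xp[i] = gp[c] * ip[c] *
          (dp[i] - dbp[c] / M - hp[i] * (dgp[c] / M));
  } else {
    for (R_xlen_t i = 0; i < n; )
      for (int c = 0; c < C; ++c, ++i) xp[i] = gp[c] * ip[c] * dp[i];
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// s-frame differencing over a (m, B) view with clip-contiguous frames.
// [[Rcpp::export]]
NumericVector batch_diff_cpp(const NumericVector& x, double m_, int B,
                             int d_per_clip, int s) {
  const R_xlen_t m = (R_xlen_t)m_;
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  for (int b = 0; b < B; ++b) {
    const int pos = b % d_per_clip;
    if (pos < s) continue;  // zero padding
    const double* cur = xp + (R_xlen_t)b * m;
    const double* prev = xp + (R_xlen_t)(b - s) * m;
    double* o = op + (R_xlen_t)b * m;
    for (R_xlen_t i = 0; i < m; ++i) o[i] = cur[i] - prev[i];
  }
  return out;
}

// Adjoint of batch_diff_cpp.
// [[Rcpp::export]]
NumericVector batch_diff_adj_cpp(const NumericVector& dm, double m_, int B,
                                 int d_per_clip, int s) {
  const R_xlen_t m = (R_xlen_t)m_;
  NumericVector dx(dm.size());
  const double* dp = dm.begin();
  double* xp = dx.begin();
  for (int b = 0; b < B; ++b) {
    const int pos = b % d_per_clip;
    double* o = xp + (R_xlen_t)b * m;
    if (pos >= s) {
      const double* d1 = dp + (R_xlen_t)b * m;
      for (R_xlen_t i = 0; i < m; ++i) o[i] += d1[i];
    }
    if (pos + s < d_per_clip) {
      const double* d2 = dp + (R_xlen_t)(b + s) * m;
      for (R_xlen_t i = 0; i < m; ++i) o[i] -= d2[i];
    }
  }
  return dx;
}
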