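#include <Rcpp.h>
using namespace Rcpp;

// Feature-map batches are stored as (H*W*N) x C numeric matrices with the
// 0-based row index r = h + H*(w + W*n): column-major spatial layout per
// sample, samples stacked along rows, one column per channel.  The 1x1
// stages of a TETDia block then reduce to plain matrix products; only the
// spatial (depthwise) convolution and pooling need explicit indexing, which
// lives here.

static inline int out_len(int L, int dk, int stride, int pad) {
  return (L + 2 * pad - dk) / stride + 1;
}

// Depthwise (channel-grouped, one filter per channel) convolution forward.
// weights: (dk*dk) x C, kernel stored column-major (i + dk*j).
// [[Rcpp::export(name = ".dw_conv_forward")]]
NumericMatrix dw_conv_forward(NumericMatrix x, int H, int W, int N,
                              NumericMatrix weights, int dk, int stride,
                              int pad) {
  const int C = x.ncol();
  if (weights.ncol() != C) stop("filter count does not match channel count");
  const int Ho = out_len(H, dk, stride, pad);
  const int Wo = out_len(W, dk, stride, pad);
  NumericMatrix out(Rcpp::no_init(Ho * Wo * N, C));
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    const double* k = &weights(0, c);
    double* oc = &out(0, c);
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + (R_xlen_t)n * H * W;
      double* on = oc + (R_xlen_t)n * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * stride - pad;
        const int j0 = w0 < 0 ? -w0 : 0;
        const int j1 = (w0 + dk > W) ? W - w0 : dk;
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride - pad;
          const int i0 = h0 < 0 ? -h0 : 0;
          const int i1 = (h0 + dk > H) ? H - h0 : dk;
          double acc = 0.0;
          for (int j = j0; j < j1; ++j) {
            const double* col = xn + (R_xlen_t)(w0 + j) * H + h0;
            const double* kj = k + j * dk;
            for (int i = i0; i < i1; ++i) acc += kj[i] * col[i];
          }
          on[ho + Ho * wo] = acc;
        }
      }
    }
  }
  return out;
}

// Gradient w.r.t. the input of the depthwise convolution.
// [[Rcpp::export(name = ".dw_conv_backward_input")]]
NumericMatrix dw_conv_backward_input(NumericMatrix dy, int H, int W, int N,
                                     NumericMatrix weights, int dk, int stride,
                                     int pad) {
  const int C = dy.ncol();
  const int Ho = out_len(H, dk, stride, pad);
  const int Wo = out_len(W, dk, stride, pad);
  NumericMatrix dx(H * W * N, C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dy(0, c);
    const double* k = &weights(0, c);
    double* dxc = &dx(0, c);
    for (int n = 0; n < N; ++n) {
      const double* dyn = dyc + (R_xlen_t)n * Ho * Wo;
      double* dxn = dxc + (R_xlen_t)n * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * stride - pad;
        const int j0 = w0 < 0 ? -w0 : 0;
        const int j1 = (w0 + dk > W) ? W - w0 : dk;
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride - pad;
          const int i0 = h0 < 0 ? -h0 : 0;
          const int i1 = (h0 + dk > H) ? H - h0 : dk;
          const double g = dyn[ho + Ho * wo];
          if (g == 0.0) continue;
          for (int j = j0; j < j1; ++j) {
            double* col = dxn + (R_xlen_t)(w0 + j) * H + h0;
            const double* kj = k + j * dk;
            for (int i = i0; i < i1; ++i) col[i] += g * kj[i];
          }
        }
      }
    }
  }
  return dx;
}

// Gradient w.r.t. the depthwise kernel weights.
// [[Rcpp::export(name = ".dw_conv_backward_weight")]]
NumericMatrix dw_conv_backward_weight(NumericMatrix x, NumericMatrix dy,
                                      int H, int W, int N, int dk, int stride,
                                      int pad) {
  const int C = x.ncol();
  const int Ho = out_len(H, dk, stride, pad);
  const int Wo = out_len(W, dk, stride, pad);
  NumericMatrix dw(dk * dk, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    const double* dyc = &dy(0, c);
    double* dwc = &dw(0, c);
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + (R_xlen_t)n * H * W;
      const double* dyn = dyc + (R_xlen_t)n * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * stride - pad;
        const int j0 = w0 < 0 ? -w0 : 0;
        const int j1 = (w0 + dk > W) ? W - w0 : dk;
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride - pad;
          const int i0 = h0 < 0 ? -h0 : 0;
          const int i1 = (h0 + dk > H) ? H - h0 : dk;
          const double g = dyn[ho + Ho * wo];
          if (g == 0.0) continue;
          for (int j = j0; j < j1; ++j) {
            const double* col = xn + (R_xlen_t)(w0 + j) * H + h0;
            double* dwj = dwc + j * dk;
            for (int i = i0; i < i1; ++i) dwj[i] += g * col[i];
          }
        }
      }
    }
  }
  return dw;
}

// Max pooling forward; padding uses -Inf so padded cells never win.
// Returns the pooled map and the 0-based input row index of each winner.
// [[Rcpp::export(name = ".max_pool_forward")]]
List max_pool_forward(NumericMatrix x, int H, int W, int N, int k, int stride,
                      int pad) {
  const int C = x.ncol();
  const int Ho = out_len(H, k, stride, pad);
  const int Wo = out_len(W, k, stride, pad);
  NumericMatrix out(Ho * Wo * N, C);
  IntegerMatrix arg(Ho * Wo * N, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int n = 0; n < N; ++n) {
      const R_xlen_t xoff = (R_xlen_t)n * H * W;
      const R_xlen_t ooff = (R_xlen_t)n * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * stride - pad;
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride - pad;
          double best = R_NegInf;
          int best_idx = -1;
          for (int j = 0; j < k; ++j) {
            const int w = w0 + j;
            if (w < 0 || w >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int h = h0 + i;
              if (h < 0 || h >= H) continue;
              const double v = xc[xoff + h + (R_xlen_t)w * H];
              if (v > best) { best = v; best_idx = h + w * H; }
            }
          }
          out(ooff + ho + Ho * wo, c) = best;
          arg(ooff + ho + Ho * wo, c) = (int)(xoff + best_idx);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".max_pool_backward")]]
NumericMatrix max_pool_backward(NumericMatrix dy, IntegerMatrix argmax,
                                int H, int W, int N) {
  const int C = dy.ncol();
  NumericMatrix dx(H * W * N, C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dy(0, c);
    const int* ac = &argmax(0, c);
    double* dxc = &dx(0, c);
    const R_xlen_t M = dy.nrow();
    for (R_xlen_t r = 0; r < M; ++r) dxc[ac[r]] += dyc[r];
  }
  return dx;
}

// ---- fused elementwise helpers (avoid sweep()'s aperm overhead) ----------

// y[r,c] = x[r,c] * scale[c] + shift[c]
// [[Rcpp::export(name = ".col_affine")]]
NumericMatrix col_affine(NumericMatrix x, NumericVector scale,
                         NumericVector shift) {
  const R_xlen_t n = x.nrow(); const int C = x.ncol();
  NumericMatrix y(Rcpp::no_init(n, C));
  for (int c = 0; c < C; ++c) {
    const double s = scale[c], t = shift[c];
    const double* xc = &x(0, c); double* yc = &y(0, c);
    for (R_xlen_t r = 0; r < n; ++r) yc[r] = xc[r] * s + t;
  }
  return y;
}

// Per-column mean and (biased) variance in one pass.
// [[Rcpp::export(name = ".col_mean_var")]]
List col_mean_var(NumericMatrix x) {
  const R_xlen_t n = x.nrow(); const int C = x.ncol();
  NumericVector mu(C), v(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double s = 0, s2 = 0;
    for (R_xlen_t r = 0; r < n; ++r) { s += xc[r]; s2 += xc[r] * xc[r]; }
    mu[c] = s / n;
    v[c] = s2 / n - mu[c] * mu[c];
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// Batch-norm backward, fused: given dy, xhat, and gi = gamma * istd,
// computes dx = (dy - mean(dy) - xhat * mean(dy*xhat)) * gi plus the
// parameter gradients colSums(dy*xhat) and colSums(dy).
// [[Rcpp::export(name = ".bn_backward")]]
List bn_backward(NumericMatrix dy, NumericMatrix xhat, NumericVector gi) {
  const R_xlen_t n = dy.nrow(); const int C = dy.ncol();
  NumericMatrix dx(Rcpp::no_init(n, C));
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dy(0, c); const double* xh = &xhat(0, c);
    double s1 = 0, s2 = 0;
    for (R_xlen_t r = 0; r < n; ++r) { s1 += dyc[r]; s2 += dyc[r] * xh[r]; }
    dbeta[c] = s1; dgamma[c] = s2;
    const double m1 = s1 / n, m2 = s2 / n, g = gi[c];
    double* dxc = &dx(0, c);
    for (R_xlen_t r = 0; r < n; ++r)
      dxc[r] = (dyc[r] - m1 - xh[r] * m2) * g;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_forward")]]
NumericMatrix relu_forward(NumericMatrix x) {
  const R_xlen_t m = (R_xlen_t)x.nrow() * x.ncol();
  NumericMatrix y(Rcpp::no_init(x.nrow(), x.ncol()));
  const double* xp = x.begin(); double* yp = y.begin();
  for (R_xlen_t i = 0; i < m; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// dx = dy * (out > 0)
// [[Rcpp::export(name = ".relu_backward")]]
NumericMatrix relu_backward(NumericMatrix dy, NumericMatrix out) {
  const R_xlen_t m = (R_xlen_t)dy.nrow() * dy.ncol();
  NumericMatrix dx(Rcpp::no_init(dy.nrow(), dy.ncol()));
  const double* dp = dy.begin(); const double* op = out.begin();
  double* xp = dx.begin();
  for (R_xlen_t i = 0; i < m; ++i) xp[i] = op[i] > 0 ? dp[i] : 0;
  return dx;
}

// y[r,c] = x[r,c] + b[c]
// [[Rcpp::export(name = ".col_add")]]
NumericMatrix col_add(NumericMatrix x, NumericVector b) {
  const R_xlen_t n = x.nrow(); const int C = x.ncol();
  NumericMatrix y(Rcpp::no_init(n, C));
  for (int c = 0; c < C; ++c) {
    const double bc = b[c];
    const double* xc = &x(0, c); double* yc = &y(0, c);
    for (R_xlen_t r = 0; r < n; ++r) yc[r] = xc[r] + bc;
  }
  return y;
}

// Fused batch-norm + ReLU forward: y = max(gamma*(x-mu)*istd + beta, 0).
// [[Rcpp::export(name = ".bnrelu_forward")]]
NumericMatrix bnrelu_forward(NumericMatrix x, NumericVector scale,
                             NumericVector shift) {
  const R_xlen_t n = x.nrow(); const int C = x.ncol();
  NumericMatrix y(Rcpp::no_init(n, C));
  for (int c = 0; c < C; ++c) {
    const double s = scale[c], t = shift[c];
    const double* xc = &x(0, c); double* yc = &y(0, c);
    for (R_xlen_t r = 0; r < n; ++r) {
      const double v = xc[r] * s + t;
      yc[r] = v > 0 ? v : 0;
    }
  }
  return y;
}

// Fused ReLU + batch-norm backward.  out is the post-ReLU output; the
// gradient is masked by out > 0, then propagated through the normalization.
// [[Rcpp::export(name = ".bnrelu_backward")]]
List bnrelu_backward(NumericMatrix dy, NumericMatrix out, NumericMatrix x,
                     NumericVector mu, NumericVector istd,
                     NumericVector gamma) {
  const R_xlen_t n = dy.nrow(); const int C = dy.ncol();
  NumericMatrix dx(Rcpp::no_init(n, C));
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = istd[c], g = gamma[c];
    const double* dyc = &dy(0, c); const double* oc = &out(0, c);
    const double* xc = &x(0, c);
    double s1 = 0, s2 = 0;
    for (R_xlen_t r = 0; r < n; ++r) {
      if (oc[r] > 0) {
        const double d = dyc[r];
        s1 += d;
        s2 += d * (xc[r] - m) * is;
      }
    }
    dbeta[c] = s1; dgamma[c] = s2;
    const double m1 = s1 / n, m2 = s2 / n, gi = g * is;
    double* dxc = &dx(0, c);
    for (R_xlen_t r = 0; r < n; ++r) {
      const double d = oc[r] > 0 ? dyc[r] : 0;
      dxc[r] = (d - m1 - (xc[r] - m) * is * m2) * gi;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
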