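#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Tensors are numeric arrays with dim (C, H, W, N), column-major:
// linear index = c + C*(h + H*(w + W*n)).
// im2col rows are ordered r = c + C*(dy + kh*dx); columns col = oy + oH*(ox + oW*n),
// so `Wmat %*% cols` (Wmat: Cout x C*kh*kw) yields an array (Cout, oH, oW, N)
// directly, with no permutation.

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, int C, int H, int W, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int oH = out_size(H, kh, sh, ph), oW = out_size(W, kw, sw, pw);
  const int R = C * kh * kw;
  NumericMatrix cols(R, oH * oW * N);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < oW; ++ox) {
      for (int oy = 0; oy < oH; ++oy) {
        const R_xlen_t col = (R_xlen_t)oy + (R_xlen_t)oH * (ox + (R_xlen_t)oW * n);
        double* dst = cp + col * R;
        const int h0 = oy * sh - ph;
        for (int dx = 0; dx < kw; ++dx) {
          const int w = ox * sw - pw + dx;
          double* d = dst + (R_xlen_t)C * kh * dx;
          if (w >= 0 && w < W && h0 >= 0 && h0 + kh <= H) {
            // (c, dy) block is contiguous in source and destination
            const double* s = xp + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w + (R_xlen_t)W * n));
            std::memcpy(d, s, sizeof(double) * (size_t)C * kh);
            continue;
          }
          for (int dy = 0; dy < kh; ++dy) {
            const int h = h0 + dy;
            double* dd = d + (R_xlen_t)C * dy;
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) dd[c] = 0.0;
            } else {
              const double* s = xp + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              for (int c = 0; c < C; ++c) dd[c] = s[c];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Inverse scatter-add of cpp_im2col; used for the conv gradient wrt its input.
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& cols, int C, int H, int W, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int oH = out_size(H, kh, sh, ph), oW = out_size(W, kw, sw, pw);
  const int R = C * kh * kw;
  NumericVector x((R_xlen_t)C * H * W * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < oW; ++ox) {
      for (int oy = 0; oy < oH; ++oy) {
        const R_xlen_t col = (R_xlen_t)oy + (R_xlen_t)oH * (ox + (R_xlen_t)oW * n);
        const double* src = cp + col * R;
        for (int dx = 0; dx < kw; ++dx) {
          const int w = ox * sw - pw + dx;
          if (w < 0 || w >= W) continue;
          for (int dy = 0; dy < kh; ++dy) {
            const int h = oy * sh - ph + dy;
            if (h < 0 || h >= H) continue;
            const double* s = src + (R_xlen_t)C * (dy + kh * dx);
            double* d = xp + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(C, H, W, N);
  return x;
}

// Max pooling with argmax bookkeeping (1-based linear indices into the input).
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericVector& x, int C, int H, int W, int N,
                     int k, int s, int p) {
  const int oH = out_size(H, k, s, p), oW = out_size(W, k, s, p);
  NumericVector out((R_xlen_t)C * oH * oW * N);
  IntegerVector arg((R_xlen_t)C * oH * oW * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < oW; ++ox) {
      for (int oy = 0; oy < oH; ++oy) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int dx = 0; dx < k; ++dx) {
            const int w = ox * s - p + dx;
            if (w < 0 || w >= W) continue;
            for (int dy = 0; dy < k; ++dy) {
              const int h = oy * s - p + dy;
              if (h < 0 || h >= H) continue;
              const R_xlen_t idx = c + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          const R_xlen_t o = c + (R_xlen_t)C * (oy + (R_xlen_t)oH * (ox + (R_xlen_t)oW * n));
          op[o] = best;
          ap[o] = (int)(besti + 1);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, oH, oW, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(const NumericVector& dout, const IntegerVector& argmax,
                              int C, int H, int W, int N) {
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* dp = dx.begin();
  const double* gp = dout.begin();
  const int* ap = argmax.begin();
  const R_xlen_t m = dout.size();
  for (R_xlen_t i = 0; i < m; ++i) dp[ap[i] - 1] += gp[i];
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}

// Spatial global average pool: (C,H,W,N) -> C x N.
// [[Rcpp::export]]
NumericMatrix cpp_gap(const NumericVector& x, int C, int H, int W, int N) {
  NumericMatrix g(C, N);
  const double* xp = x.begin();
  const double inv = 1.0 / ((double)H * W);
  for (int n = 0; n < N; ++n) {
    double* gc = &g(0, n);
    for (R_xlen_t hw = 0; hw < (R_xlen_t)H * W; ++hw) {
      const double* s = xp + (R_xlen_t)C * (hw + (R_xlen_t)H * W * n);
      for (int c = 0; c < C; ++c) gc[c] += s[c];
    }
    for (int c = 0; c < C; ++c) gc[c] *= inv;
  }
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_gap_bwd(const NumericMatrix& dg, int C, int H, int W, int N) {
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* dp = dx.begin();
  const double inv = 1.0 / ((double)H * W);
  for (int n = 0; n < N; ++n) {
    const double* g = &dg(0, n);
    for (R_xlen_t hw = 0; hw < (R_xlen_t)H * W; ++hw) {
      double* d = dp + (R_xlen_t)C * (hw + (R_xlen_t)H * W * n);
      for (int c = 0; c < C; ++c) d[c] = g[c] * inv;
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}

// y[c,h,w,n] = x[c,h,w,n] * w[c,n]  (per-channel, per-sample broadcast)
// [[Rcpp::export]]
NumericVector cpp_chanmul(const NumericVector& x, const NumericMatrix& w,
                          int C, int H, int W, int N) {
  NumericVector y((R_xlen_t)C * H * W * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* wc = &w(0, n);
    for (R_xlen_t hw = 0; hw < (R_xlen_t)H * W; ++hw) {
      const R_xlen_t off = (R_xlen_t)C * (hw + (R_xlen_t)H * W * n);
      for (int c = 0; c < C; ++c) yp[off + c] = xp[off + c] * wc[c];
    }
  }
  y.attr("dim") = IntegerVector::create(C, H, W, N);
  return y;
}

// In-place Adam update on the flat parameter/moment vectors (one fused pass,
// no temporaries; the vectors are owned exclusively by the optimiser state).
// [[Rcpp::export]]
void cpp_adam_update(NumericVector w, NumericVector m, NumericVector v,
                     const NumericVector& g, double alpha, double b1,
                     double b2, double eps) {
  const R_xlen_t n = w.size();
  double* wp = w.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  const double* gp = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    wp[i] -= alpha * mp[i] / (std::sqrt(vp[i]) + eps);
  }
}

// out[c,n] = sum_{h,w} a[c,h,w,n] * b[c,h,w,n]; gradient of chanmul wrt w.
// [[Rcpp::export]]
NumericMatrix cpp_chansum_prod(const NumericVector& a, const NumericVector& b,
                               int C, int H, int W, int N) {
  NumericMatrix g(C, N);
  const double* ap = a.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n) {
    double* gc = &g(0, n);
    for (R_xlen_t hw = 0; hw < (R_xlen_t)H * W; ++hw) {
      const R_xlen_t off = (R_xlen_t)C * (hw + (R_xlen_t)H * W * n);
      for (int c = 0; c < C; ++c) gc[c] += ap[off + c] * bp[off + c];
    }
  }
  return g;
}
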