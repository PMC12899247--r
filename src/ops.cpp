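#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are numeric arrays with dim (H, W, C, B), column-major.
// Direct-path convolution weights are (k, k, Cin/g, Cout) arrays.

static inline int out_size(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// valid output range [lo, hi) for input index i = o*stride + off in [0, n)
static inline void valid_range(int off, int stride, int n, int nout,
                               int &lo, int &hi) {
  lo = off < 0 ? (-off + stride - 1) / stride : 0;
  hi = (n - off + stride - 1) / stride;
  if (hi > nout) hi = nout;
  if (lo > hi) lo = hi;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector dims, int k,
                         int stride, int pad, int dil) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const int nrow = C * k * k;
  NumericMatrix cols(nrow, (R_xlen_t)Ho * Wo * B);
  const double *px = x.begin();
  double *pc = cols.begin();
  std::vector<int> khlo(Ho), khhi(Ho);
  for (int ho = 0; ho < Ho; ++ho) {
    const int hi0 = ho * stride - pad;
    int lo = hi0 < 0 ? (-hi0 + dil - 1) / dil : 0;
    int hi = (H - 1 - hi0) / dil + 1;
    if (hi > k) hi = k;
    if (lo > hi) lo = hi;
    khlo[ho] = lo; khhi[ho] = hi;
  }
  for (int b = 0; b < B; ++b) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t colidx = (R_xlen_t)b * Ho * Wo +
          (R_xlen_t)wo * Ho + ho;
        double *dcol = pc + colidx * nrow;
        const int lo = khlo[ho], hi = khhi[ho];
        const int hbase = ho * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *sc = px + ((R_xlen_t)b * C + c) * H * W;
          double *dst = dcol + c * k * k;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride - pad + kw * dil;
            if (wi < 0 || wi >= W) continue;
            const double *scol = sc + (R_xlen_t)wi * H + hbase;
            double *d2 = dst + kw * k;
            for (int kh = lo; kh < hi; ++kh)
              d2[kh] = scol[kh * dil];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, IntegerVector dims, int k,
                         int stride, int pad, int dil) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const int nrow = C * k * k;
  NumericVector x((R_xlen_t)H * W * C * B);
  const double *pc = cols.begin();
  double *px = x.begin();
  for (int b = 0; b < B; ++b) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int kw = 0; kw < k; ++kw) {
        const int wi = wo * stride - pad + kw * dil;
        if (wi < 0 || wi >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          const int off = -pad + kh * dil;
          int lo, hi;
          valid_range(off, stride, H, Ho, lo, hi);
          for (int c = 0; c < C; ++c) {
            double *dst = px + ((R_xlen_t)b * C + c) * H * W +
              (R_xlen_t)wi * H;
            const double *src = pc +
              ((R_xlen_t)b * Ho * Wo + (R_xlen_t)wo * Ho) * nrow +
              c * k * k + kw * k + kh;
            for (int ho = lo; ho < hi; ++ho)
              dst[ho * stride + off] += src[(R_xlen_t)ho * nrow];
          }
        }
      }
    }
  }
  x.attr("dim") = dims;
  return x;
}

// Direct grouped convolution; weight array dim (k, k, Cin/g, Cout).
// [[Rcpp::export]]
NumericVector gconv_fwd_cpp(NumericVector x, IntegerVector dims,
                            NumericVector w, int cout, int k, int stride,
                            int pad, int dil, int groups) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const int cing = C / groups, coutg = cout / groups;
  NumericVector y((R_xlen_t)Ho * Wo * cout * B);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < cout; ++co) {
      const int g = co / coutg;
      double *dst = py + ((R_xlen_t)b * cout + co) * Ho * Wo;
      for (int ci = 0; ci < cing; ++ci) {
        const int c = g * cing + ci;
        const double *src = px + ((R_xlen_t)b * C + c) * H * W;
        const double *wk = pw + ((R_xlen_t)co * cing + ci) * k * k;
        for (int wo = 0; wo < Wo; ++wo) {
          double *dcol = dst + (R_xlen_t)wo * Ho;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride - pad + kw * dil;
            if (wi < 0 || wi >= W) continue;
            const double *scol = src + (R_xlen_t)wi * H;
            for (int kh = 0; kh < k; ++kh) {
              const double wv = wk[kw * k + kh];
              if (wv == 0.0) continue;
              const int off = -pad + kh * dil;
              int lo, hi;
              valid_range(off, stride, H, Ho, lo, hi);
              for (int ho = lo; ho < hi; ++ho)
                dcol[ho] += wv * scol[ho * stride + off];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, B);
  return y;
}

// [[Rcpp::export]]
NumericVector gconv_bwd_x_cpp(NumericVector dy, IntegerVector dims,
                              NumericVector w, int cout, int k, int stride,
                              int pad, int dil, int groups) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const int cing = C / groups, coutg = cout / groups;
  NumericVector dx((R_xlen_t)H * W * C * B);
  const double *pdy = dy.begin(), *pw = w.begin();
  double *pdx = dx.begin();
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < cout; ++co) {
      const int g = co / coutg;
      const double *src = pdy + ((R_xlen_t)b * cout + co) * Ho * Wo;
      for (int ci = 0; ci < cing; ++ci) {
        const int c = g * cing + ci;
        double *dst = pdx + ((R_xlen_t)b * C + c) * H * W;
        const double *wk = pw + ((R_xlen_t)co * cing + ci) * k * k;
        for (int wo = 0; wo < Wo; ++wo) {
          const double *scol = src + (R_xlen_t)wo * Ho;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride - pad + kw * dil;
            if (wi < 0 || wi >= W) continue;
            double *dcol = dst + (R_xlen_t)wi * H;
            for (int kh = 0; kh < k; ++kh) {
              const double wv = wk[kw * k + kh];
              if (wv == 0.0) continue;
              const int off = -pad + kh * dil;
              int lo, hi;
              valid_range(off, stride, H, Ho, lo, hi);
              for (int ho = lo; ho < hi; ++ho)
                dcol[ho * stride + off] += wv * scol[ho];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return dx;
}

// [[Rcpp::export]]
NumericVector gconv_bwd_w_cpp(NumericVector x, IntegerVector dims,
                              NumericVector dy, int cout, int k, int stride,
                              int pad, int dil, int groups) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const int cing = C / groups, coutg = cout / groups;
  NumericVector dw((R_xlen_t)k * k * cing * cout);
  const double *px = x.begin(), *pdy = dy.begin();
  double *pdw = dw.begin();
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < cout; ++co) {
      const int g = co / coutg;
      const double *sdy = pdy + ((R_xlen_t)b * cout + co) * Ho * Wo;
      for (int ci = 0; ci < cing; ++ci) {
        const int c = g * cing + ci;
        const double *sx = px + ((R_xlen_t)b * C + c) * H * W;
        double *wk = pdw + ((R_xlen_t)co * cing + ci) * k * k;
        for (int kw = 0; kw < k; ++kw) {
          for (int kh = 0; kh < k; ++kh) {
            const int off = -pad + kh * dil;
            int lo, hi;
            valid_range(off, stride, H, Ho, lo, hi);
            double acc = 0.0;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo * stride - pad + kw * dil;
              if (wi < 0 || wi >= W) continue;
              const double *xcol = sx + (R_xlen_t)wi * H;
              const double *ycol = sdy + (R_xlen_t)wo * Ho;
              for (int ho = lo; ho < hi; ++ho)
                acc += xcol[ho * stride + off] * ycol[ho];
            }
            wk[kw * k + kh] += acc;
          }
        }
      }
    }
  }
  dw.attr("dim") = IntegerVector::create(k, k, cing, cout);
  return dw;
}

// Stride-1 max pooling with shape-preserving padding; records argmax for
// the backward pass (1-based flat index into the input array).
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, IntegerVector dims, int k) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int pad = (k - 1) / 2;
  NumericVector y((R_xlen_t)H * W * C * B);
  IntegerVector idx((R_xlen_t)H * W * C * B);
  const double *px = x.begin();
  double *py = y.begin();
  int *pi = idx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)b * C + c) * H * W;
      for (int wo = 0; wo < W; ++wo) {
        const int w0 = wo - pad < 0 ? 0 : wo - pad;
        const int w1 = wo + pad >= W ? W - 1 : wo + pad;
        for (int ho = 0; ho < H; ++ho) {
          const int h0 = ho - pad < 0 ? 0 : ho - pad;
          const int h1 = ho + pad >= H ? H - 1 : ho + pad;
          double best = R_NegInf;
          R_xlen_t bi = -1;
          for (int wi = w0; wi <= w1; ++wi) {
            const double *col = px + base + (R_xlen_t)wi * H;
            for (int hi = h0; hi <= h1; ++hi)
              if (col[hi] > best) { best = col[hi];
                bi = base + (R_xlen_t)wi * H + hi; }
          }
          const R_xlen_t o = base + (R_xlen_t)wo * H + ho;
          py[o] = best;
          pi[o] = (int)(bi + 1);
        }
      }
    }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector idx,
                              IntegerVector dims) {
  NumericVector dx((R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3]);
  const double *pdy = dy.begin();
  const int *pi = idx.begin();
  double *pdx = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) pdx[pi[i] - 1] += pdy[i];
  dx.attr("dim") = dims;
  return dx;
}

// Per-pixel mean and max over channels -> (H, W, 2, B); channel 1 = mean,
// channel 2 = max. Argmax channel recorded for the backward pass.
// [[Rcpp::export]]
List chpool_fwd_cpp(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const R_xlen_t hw = (R_xlen_t)H * W;
  NumericVector y(hw * 2 * B);
  IntegerVector amax(hw * B);
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = amax.begin();
  for (int b = 0; b < B; ++b) {
    double *ymean = py + (R_xlen_t)b * 2 * hw;
    double *ymax = ymean + hw;
    int *am = pa + (R_xlen_t)b * hw;
    for (R_xlen_t p = 0; p < hw; ++p) {
      double s = 0.0, m = R_NegInf;
      int mi = 0;
      for (int c = 0; c < C; ++c) {
        const double v = px[((R_xlen_t)b * C + c) * hw + p];
        s += v;
        if (v > m) { m = v; mi = c; }
      }
      ymean[p] = s / C;
      ymax[p] = m;
      am[p] = mi + 1;
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, 2, B);
  return List::create(_["y"] = y, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector chpool_bwd_cpp(NumericVector dy, IntegerVector amax,
                             IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const R_xlen_t hw = (R_xlen_t)H * W;
  NumericVector dx((R_xlen_t)H * W * C * B);
  const double *pdy = dy.begin();
  const int *pa = amax.begin();
  double *pdx = dx.begin();
  for (int b = 0; b < B; ++b) {
    const double *dmean = pdy + (R_xlen_t)b * 2 * hw;
    const double *dmax = dmean + hw;
    const int *am = pa + (R_xlen_t)b * hw;
    for (R_xlen_t p = 0; p < hw; ++p) {
      const double g = dmean[p] / C;
      for (int c = 0; c < C; ++c) pdx[((R_xlen_t)b * C + c) * hw + p] += g;
      pdx[((R_xlen_t)b * C + (am[p] - 1)) * hw + p] += dmax[p];
    }
  }
  dx.attr("dim") = dims;
  return dx;
}
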