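#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Array layout is column-major (H, W, C, N): index h + H*(w + W*(c + C*n)).
// Weights are (kh, kw, Cin/groups, Cout).  All loops are plain and
// single-threaded; sizes in this package are small enough that cache
// behaviour, not vectorisation, dominates.

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector wgt, IntegerVector wdim,
                             NumericVector bias,
                             int stride, int ph, int pw, int groups) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cpg = wdim[2], Cout = wdim[3];
  const int coutpg = Cout / groups;
  const int Ho = (H + 2 * ph - kh) / stride + 1;
  const int Wo = (W + 2 * pw - kw) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  const double* xp = x.begin();
  const double* wp = wgt.begin();
  double* yp = y.begin();
  const bool has_b = bias.size() == Cout;
  // shift-and-accumulate: for each kernel tap, add the weighted shifted
  // input plane to the output plane over the tap's valid index range --
  // branch-free contiguous inner loops.
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const int g = co / coutpg;
      double* ytile = yp + static_cast<R_xlen_t>(Ho) * Wo * (co + static_cast<R_xlen_t>(Cout) * n);
      const double b = has_b ? bias[co] : 0.0;
      for (int i = 0; i < Ho * Wo; ++i) ytile[i] = b;
      for (int cl = 0; cl < cpg; ++cl) {
        const int ci = g * cpg + cl;
        const double* xtile = xp + static_cast<R_xlen_t>(H) * W * (ci + static_cast<R_xlen_t>(Cin) * n);
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const double wv = wp[i + kh * (j + kw * (cl + cpg * co))];
            if (wv == 0.0) continue;
            // valid ho: 0 <= ho*stride - ph + i < H
            int ho_lo = (ph - i + stride - 1) / stride; if (ho_lo < 0) ho_lo = 0;
            int ho_hi = (H - 1 + ph - i) / stride;      if (ho_hi > Ho - 1) ho_hi = Ho - 1;
            int wo_lo = (pw - j + stride - 1) / stride; if (wo_lo < 0) wo_lo = 0;
            int wo_hi = (W - 1 + pw - j) / stride;      if (wo_hi > Wo - 1) wo_hi = Wo - 1;
            if (ho_hi < ho_lo || wo_hi < wo_lo) continue;
            for (int wo = wo_lo; wo <= wo_hi; ++wo) {
              const int wi = wo * stride - pw + j;
              double* yc = ytile + static_cast<R_xlen_t>(Ho) * wo;
              const double* xc = xtile + static_cast<R_xlen_t>(H) * wi - ph + i;
              if (stride == 1) {
                for (int ho = ho_lo; ho <= ho_hi; ++ho)
                  yc[ho] += wv * xc[ho];
              } else {
                for (int ho = ho_lo; ho <= ho_hi; ++ho)
                  yc[ho] += wv * xc[static_cast<R_xlen_t>(ho) * stride];
              }
            }
          }
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector wgt, IntegerVector wdim,
                    NumericVector gy, IntegerVector ydim,
                    int stride, int ph, int pw, int groups, bool has_bias) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cpg = wdim[2], Cout = wdim[3];
  const int Ho = ydim[0], Wo = ydim[1];
  const int coutpg = Cout / groups;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * Cin * N);
  NumericVector gw(static_cast<R_xlen_t>(kh) * kw * cpg * Cout);
  NumericVector gb(has_bias ? Cout : 0);
  const double* xp = x.begin();
  const double* wp = wgt.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const int g = co / coutpg;
      const double* gtile = gyp + static_cast<R_xlen_t>(Ho) * Wo * (co + static_cast<R_xlen_t>(Cout) * n);
      if (has_bias) {
        double acc = 0.0;
        for (int i = 0; i < Ho * Wo; ++i) acc += gtile[i];
        gb[co] += acc;
      }
      for (int cl = 0; cl < cpg; ++cl) {
        const int ci = g * cpg + cl;
        const double* xtile = xp + static_cast<R_xlen_t>(H) * W * (ci + static_cast<R_xlen_t>(Cin) * n);
        double* gxtile = gxp + static_cast<R_xlen_t>(H) * W * (ci + static_cast<R_xlen_t>(Cin) * n);
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const int widx = i + kh * (j + kw * (cl + cpg * co));
            const double wv = wp[widx];
            double wacc = 0.0;
            int ho_lo = (ph - i + stride - 1) / stride; if (ho_lo < 0) ho_lo = 0;
            int ho_hi = (H - 1 + ph - i) / stride;      if (ho_hi > Ho - 1) ho_hi = Ho - 1;
            int wo_lo = (pw - j + stride - 1) / stride; if (wo_lo < 0) wo_lo = 0;
            int wo_hi = (W - 1 + pw - j) / stride;      if (wo_hi > Wo - 1) wo_hi = Wo - 1;
            if (ho_hi < ho_lo || wo_hi < wo_lo) continue;
            for (int wo = wo_lo; wo <= wo_hi; ++wo) {
              const int wi = wo * stride - pw + j;
              const double* gc = gtile + static_cast<R_xlen_t>(Ho) * wo;
              const double* xc = xtile + static_cast<R_xlen_t>(H) * wi - ph + i;
              double* gxc = gxp == 0 ? 0 : gxtile + static_cast<R_xlen_t>(H) * wi - ph + i;
              if (stride == 1) {
                for (int ho = ho_lo; ho <= ho_hi; ++ho) {
                  wacc += xc[ho] * gc[ho];
                  gxc[ho] += wv * gc[ho];
                }
              } else {
                for (int ho = ho_lo; ho <= ho_hi; ++ho) {
                  wacc += xc[static_cast<R_xlen_t>(ho) * stride] * gc[ho];
                  gxc[static_cast<R_xlen_t>(ho) * stride] += wv * gc[ho];
                }
              }
            }
            gwp[widx] += wacc;
          }
      }
    }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling; returns the pooled values and, per output cell, the linear
// (0-based) index of the winning input element (-1 if the window saw only
// padding).
// [[Rcpp::export]]
List maxpool2d_fwd_cpp(NumericVector x, IntegerVector xdim,
                       int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector arg(y.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -DBL_MAX; int bi = -1;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              const int xi = idx4(hi, wi, c, n, H, W, C);
              if (x[xi] > best) { best = x[xi]; bi = xi; }
            }
          }
          const int yi = idx4(ho, wo, c, n, Ho, Wo, C);
          y[yi] = (bi >= 0) ? best : 0.0;
          arg[yi] = bi;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2d_bwd_cpp(NumericVector gy, IntegerVector arg,
                                IntegerVector xdim) {
  NumericVector gx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (arg[i] >= 0) gx[arg[i]] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Average pooling dividing by the count of valid (non-padding) cells.
// [[Rcpp::export]]
NumericVector avgpool2d_fwd_cpp(NumericVector x, IntegerVector xdim,
                                int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0; int cnt = 0;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              acc += x[idx4(hi, wi, c, n, H, W, C)];
              ++cnt;
            }
          }
          y[idx4(ho, wo, c, n, Ho, Wo, C)] = cnt > 0 ? acc / cnt : 0.0;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2d_bwd_cpp(NumericVector gy, IntegerVector ydim,
                                IntegerVector xdim,
                                int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = ydim[0], Wo = ydim[1];
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int cnt = 0;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi >= 0 && hi < H) ++cnt;
            }
          }
          if (cnt == 0) continue;
          const double g = gy[idx4(ho, wo, c, n, Ho, Wo, C)] / cnt;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              gx[idx4(hi, wi, c, n, H, W, C)] += g;
            }
          }
        }
  gx.attr("dim") = xdim;
  return gx;
}
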