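#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
using namespace Rcpp;

// Tensors use the R array layout (H, W, C, N), column-major.
// Convolutions are stride-1; pooling stride equals the pool size.
// Patches are gathered per image into a reusable workspace so the peak
// resident size stays near the activation size, and the matrix products go
// through R's BLAS.

static std::vector<double> ws_patches, ws_masked;

// gather one image's kh x kw x C patches: out (R x Ho*Wo), R = kh*kw*C
static void im2col_one(const double* xc, int H, int W, int C,
                       int kh, int kw, int ph, int pw,
                       int Ho, int Wo, double* out) {
  const int R = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      double* oc = out + (R_xlen_t)(ho + Ho * wo) * R;
      for (int c = 0; c < C; ++c) {
        const double* xpc = xc + (R_xlen_t)H * W * c;
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo + kj - pw;
          const bool win = wi >= 0 && wi < W;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho + ki - ph;
            oc[ki + kh * (kj + kw * c)] =
              (win && hi >= 0 && hi < H) ? xpc[hi + (R_xlen_t)H * wi] : 0.0;
          }
        }
      }
    }
}

// y = conv(x, W) + b, optional fused ReLU. W dims (kh, kw, C, F).
// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, IntegerVector dims,
                             NumericVector Wt, IntegerVector wdims,
                             NumericVector bias, int ph, int pw,
                             bool relu) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int kh = wdims[0], kw = wdims[1], F = wdims[3];
  const int Ho = H + 2 * ph - kh + 1, Wo = W + 2 * pw - kw + 1;
  const int R = kh * kw * C, HW = Ho * Wo;
  NumericVector y((R_xlen_t)Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  if ((R_xlen_t)R * HW > (R_xlen_t)ws_patches.size())
    ws_patches.resize((R_xlen_t)R * HW);
  std::vector<double> out((R_xlen_t)HW * F);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (R_xlen_t)H * W * C * n;
    im2col_one(xn, H, W, C, kh, kw, ph, pw, Ho, Wo, ws_patches.data());
    // out (HW x F) = patches^T (HW x R) * W (R x F)
    F77_CALL(dgemm)("T", "N", &HW, &F, &R, &one, ws_patches.data(), &R,
                    Wt.begin(), &R, &zero, out.data(), &HW FCONE FCONE);
    double* yn = y.begin() + (R_xlen_t)HW * F * n;
    for (int f = 0; f < F; ++f) {
      const double bf = bias[f];
      const double* of = out.data() + (R_xlen_t)HW * f;
      double* yf = yn + (R_xlen_t)HW * f;
      if (relu)
        for (int i = 0; i < HW; ++i) {
          const double v = of[i] + bf;
          yf[i] = v > 0 ? v : 0.0;
        }
      else
        for (int i = 0; i < HW; ++i) yf[i] = of[i] + bf;
    }
  }
  return y;
}

// Gradients of the conv layer. dy dims (Ho, Wo, F, N); y is the forward
// output (used as the ReLU mask when the activation was fused).
// Returns dW, db and (when need_dx) dx.
// [[Rcpp::export]]
List conv2d_backward(NumericVector x, IntegerVector dims,
                     NumericVector Wt, IntegerVector wdims,
                     NumericVector dy, NumericVector y,
                     int ph, int pw, bool relu, bool need_dx) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int kh = wdims[0], kw = wdims[1], F = wdims[3];
  const int Ho = H + 2 * ph - kh + 1, Wo = W + 2 * pw - kw + 1;
  const int R = kh * kw * C, HW = Ho * Wo;
  NumericVector dW((R_xlen_t)R * F);
  dW.attr("dim") = wdims;
  NumericVector db(F);
  NumericVector dx(need_dx ? (R_xlen_t)H * W * C * N : 0);
  if (need_dx) dx.attr("dim") = dims;
  if ((R_xlen_t)R * HW > (R_xlen_t)ws_patches.size())
    ws_patches.resize((R_xlen_t)R * HW);
  if ((R_xlen_t)HW * F > (R_xlen_t)ws_masked.size())
    ws_masked.resize((R_xlen_t)HW * F);
  std::vector<double> dcols(need_dx ? (R_xlen_t)R * HW : 0);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (R_xlen_t)H * W * C * n;
    const double* dyn = dy.begin() + (R_xlen_t)HW * F * n;
    double* D = ws_masked.data();
    if (relu) {
      const double* yn = y.begin() + (R_xlen_t)HW * F * n;
      for (R_xlen_t i = 0; i < (R_xlen_t)HW * F; ++i)
        D[i] = yn[i] > 0 ? dyn[i] : 0.0;
    } else {
      std::copy(dyn, dyn + (R_xlen_t)HW * F, D);
    }
    im2col_one(xn, H, W, C, kh, kw, ph, pw, Ho, Wo, ws_patches.data());
    // dW += patches (R x HW) * D (HW x F)
    F77_CALL(dgemm)("N", "N", &R, &F, &HW, &one, ws_patches.data(), &R,
                    D, &HW, &one, dW.begin(), &R FCONE FCONE);
    for (int f = 0; f < F; ++f) {
      double s = 0.0;
      const double* Df = D + (R_xlen_t)HW * f;
      for (int i = 0; i < HW; ++i) s += Df[i];
      db[f] += s;
    }
    if (need_dx) {
      // dcols (R x HW) = W (R x F) * D^T (F x HW)
      F77_CALL(dgemm)("N", "T", &R, &HW, &F, &one, Wt.begin(), &R,
                      D, &HW, &zero, dcols.data(), &R FCONE FCONE);
      double* dxn = dx.begin() + (R_xlen_t)H * W * C * n;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double* cc = dcols.data() + (R_xlen_t)(ho + Ho * wo) * R;
          for (int c = 0; c < C; ++c) {
            double* dxc = dxn + (R_xlen_t)H * W * c;
            for (int kj = 0; kj < kw; ++kj) {
              const int wi = wo + kj - pw;
              if (wi < 0 || wi >= W) continue;
              for (int ki = 0; ki < kh; ++ki) {
                const int hi = ho + ki - ph;
                if (hi < 0 || hi >= H) continue;
                dxc[hi + (R_xlen_t)H * wi] += cc[ki + kh * (kj + kw * c)];
              }
            }
          }
        }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db,
                      _["dx"] = need_dx ? (SEXP)dx : R_NilValue);
}

// Per-channel batch-norm statistics and transforms, done in C++ to avoid
// activation-sized temporaries on the R heap.

// [[Rcpp::export]]
List bn_forward(NumericVector x, IntegerVector dims, NumericVector gamma,
                NumericVector beta, double eps) {
  const R_xlen_t HW = (R_xlen_t)dims[0] * dims[1];
  const int C = dims[2], N = dims[3];
  const double m = (double)HW * N;
  NumericVector mu(C), var(C), inv(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + HW * (c + (R_xlen_t)C * n);
      double s = 0.0;
      for (R_xlen_t i = 0; i < HW; ++i) s += xc[i];
      mu[c] += s;
    }
  for (int c = 0; c < C; ++c) mu[c] /= m;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + HW * (c + (R_xlen_t)C * n);
      double s = 0.0;
      for (R_xlen_t i = 0; i < HW; ++i) {
        const double d = xc[i] - mu[c];
        s += d * d;
      }
      var[c] += s;
    }
  for (int c = 0; c < C; ++c) {
    var[c] /= m;
    inv[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  NumericVector xhat(x.size()), y(x.size());
  xhat.attr("dim") = dims;
  y.attr("dim") = dims;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double* xc = x.begin() + off;
      double* hc = xhat.begin() + off;
      double* yc = y.begin() + off;
      const double mc = mu[c], ic = inv[c], gc = gamma[c], bc = beta[c];
      for (R_xlen_t i = 0; i < HW; ++i) {
        hc[i] = (xc[i] - mc) * ic;
        yc[i] = gc * hc[i] + bc;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mu,
                      _["var"] = var, _["inv"] = inv);
}

// [[Rcpp::export]]
NumericVector bn_eval(NumericVector x, IntegerVector dims,
                      NumericVector gamma, NumericVector beta,
                      NumericVector mean, NumericVector var, double eps) {
  const R_xlen_t HW = (R_xlen_t)dims[0] * dims[1];
  const int C = dims[2], N = dims[3];
  NumericVector y(x.size());
  y.attr("dim") = dims;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double* xc = x.begin() + off;
      double* yc = y.begin() + off;
      const double a = gamma[c] / std::sqrt(var[c] + eps);
      const double b = beta[c] - a * mean[c];
      for (R_xlen_t i = 0; i < HW; ++i) yc[i] = a * xc[i] + b;
    }
  return y;
}

// [[Rcpp::export]]
List bn_backward(NumericVector dy, NumericVector xhat, IntegerVector dims,
                 NumericVector gamma, NumericVector inv) {
  const R_xlen_t HW = (R_xlen_t)dims[0] * dims[1];
  const int C = dims[2], N = dims[3];
  const double m = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double* dc = dy.begin() + off;
      const double* hc = xhat.begin() + off;
      double sg = 0.0, sb = 0.0;
      for (R_xlen_t i = 0; i < HW; ++i) {
        sg += dc[i] * hc[i];
        sb += dc[i];
      }
      dgamma[c] += sg;
      dbeta[c] += sb;
    }
  NumericVector dx(dy.size());
  dx.attr("dim") = dims;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double* dc = dy.begin() + off;
      const double* hc = xhat.begin() + off;
      double* xc = dx.begin() + off;
      const double gi = gamma[c] * inv[c];
      const double mh = dgamma[c] / m, mb = dbeta[c] / m;
      for (R_xlen_t i = 0; i < HW; ++i)
        xc[i] = gi * (dc[i] - mb - hc[i] * mh);
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Max pooling with stride == pool size. ceil_mode pads the bottom/right edge
// so that every input element falls in some window (output dim =
// ceil(in/pool)); otherwise trailing elements that do not fill a window are
// dropped (output dim = floor((in - pool)/pool) + 1).
// [[Rcpp::export]]
List maxpool_forward(NumericVector x, IntegerVector dims,
                     int ph, int pw, bool ceil_mode) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = ceil_mode ? (H + ph - 1) / ph : (H - ph) / ph + 1;
  const int Wo = ceil_mode ? (W + pw - 1) / pw : (W - pw) / pw + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * ph, w0 = wo * pw;
          const int h1 = std::min(h0 + ph, H), w1 = std::min(w0 + pw, W);
          double best = R_NegInf;
          R_xlen_t besti = base + h0 + (R_xlen_t)H * w0;
          for (int wi = w0; wi < w1; ++wi)
            for (int hi = h0; hi < h1; ++hi) {
              const double v = xp[base + hi + (R_xlen_t)H * wi];
              if (v > best) { best = v; besti = base + hi + (R_xlen_t)H * wi; }
            }
          const R_xlen_t oi =
            ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (c + (R_xlen_t)C * n));
          op[oi] = best;
          ap[oi] = (int)besti;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_backward(NumericVector dout, IntegerVector argmax,
                               IntegerVector in_dims) {
  NumericVector dx((R_xlen_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3]);
  dx.attr("dim") = in_dims;
  const double* dp = dout.begin();
  const int* ap = argmax.begin();
  double* xp = dx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[ap[i]] += dp[i];
  return dx;
}
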