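// Low-level CPU kernels for the segmentation network.
//
// Tensor layout throughout: R numeric arrays with dim (H, W, C, N),
// column-major, so index (h, w, c, n) sits at h + H*(w + W*(c + C*n)).
// Convolution weights: dim (kh, kw, Cin/groups, Cout).
//
// Convolutions run as im2col + single-precision GEMM (Armadillo/BLAS);
// depthwise convolutions take a direct loop path.  Gradients recompute
// the column matrix rather than caching it, trading FLOPs for memory.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static inline int conv_out_size(int in, int pad0, int pad1, int k, int dil, int stride) {
  int eff = (k - 1) * dil + 1;
  return (in + pad0 + pad1 - eff) / stride + 1;
}

// Valid output-index range [lo, hi) for which in = out*stride - pad + off
// lies inside [0, in_size).
static inline void valid_range(int out_size, int stride, int pad, int off,
                               int in_size, int& lo, int& hi) {
  // smallest out with out*stride >= pad - off
  int lo_num = pad - off;
  lo = lo_num <= 0 ? 0 : (lo_num + stride - 1) / stride;
  // largest out with out*stride < in_size + pad - off
  int hi_num = in_size + pad - off;
  hi = hi_num <= 0 ? 0 : (hi_num + stride - 1) / stride;
  if (lo > out_size) lo = out_size;
  if (hi > out_size) hi = out_size;
  if (hi < lo) hi = lo;
}

// Gather the transposed column matrix colT (P x K) for sample n.
// K = kh*kw*Cin, P = Ho*Wo; row p = ho + Ho*wo, col k = khi + kh*(kwi + kw*ci).
// Only out-of-support edges are zeroed, and inner loops are branch-free.
static void im2colT(const double* x, int H, int W, int C, long long noff,
                    int kh, int kw, int stride, int pt, int pl, int dil,
                    int Ho, int Wo, arma::fmat& colT) {
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + noff + (long long)ci * H * W;
    for (int kwi = 0; kwi < kw; ++kwi) {
      int wlo, whi;
      valid_range(Wo, stride, pl, kwi * dil, W, wlo, whi);
      for (int khi = 0; khi < kh; ++khi) {
        const int k = khi + kh * (kwi + kw * ci);
        float* dst = colT.colptr(k);
        int hlo, hhi;
        valid_range(Ho, stride, pt, khi * dil, H, hlo, hhi);
        if (wlo > 0)
          std::memset(dst, 0, sizeof(float) * (size_t)wlo * Ho);
        if (whi < Wo)
          std::memset(dst + (long long)whi * Ho, 0,
                      sizeof(float) * (size_t)(Wo - whi) * Ho);
        for (int wo = wlo; wo < whi; ++wo) {
          const int iw = wo * stride - pl + kwi * dil;
          const double* xcol = xc + (long long)iw * H;
          float* dcol = dst + (long long)wo * Ho;
          for (int ho = 0; ho < hlo; ++ho) dcol[ho] = 0.0f;
          if (stride == 1) {
            const double* xrun = xcol - pt + khi * dil;
            for (int ho = hlo; ho < hhi; ++ho) dcol[ho] = (float)xrun[ho];
          } else {
            for (int ho = hlo; ho < hhi; ++ho)
              dcol[ho] = (float)xcol[ho * stride - pt + khi * dil];
          }
          for (int ho = hhi; ho < Ho; ++ho) dcol[ho] = 0.0f;
        }
      }
    }
  }
}

// Scatter-add rows [roff, roff+P) of dcolT back into dx for one sample
// (col2im transpose).
static void col2imT_off(const arma::fmat& dcolT, long long roff, double* dx,
                        int H, int W, int C, long long noff, int kh, int kw,
                        int stride, int pt, int pl, int dil, int Ho, int Wo) {
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + noff + (long long)ci * H * W;
    for (int kwi = 0; kwi < kw; ++kwi) {
      int wlo, whi;
      valid_range(Wo, stride, pl, kwi * dil, W, wlo, whi);
      for (int khi = 0; khi < kh; ++khi) {
        const int k = khi + kh * (kwi + kw * ci);
        const float* src = dcolT.colptr(k) + roff;
        int hlo, hhi;
        valid_range(Ho, stride, pt, khi * dil, H, hlo, hhi);
        for (int wo = wlo; wo < whi; ++wo) {
          const int iw = wo * stride - pl + kwi * dil;
          double* xcol = xc + (long long)iw * H;
          const float* scol = src + (long long)wo * Ho;
          if (stride == 1) {
            double* xrun = xcol - pt + khi * dil;
            for (int ho = hlo; ho < hhi; ++ho) xrun[ho] += (double)scol[ho];
          } else {
            for (int ho = hlo; ho < hhi; ++ho)
              xcol[ho * stride - pt + khi * dil] += (double)scol[ho];
          }
        }
      }
    }
  }
}

// Forward convolution.  When `keep_cache` is true (training), the batched
// column matrix is retained and returned as an external pointer so the
// backward pass can skip the gather; the result is then a list(y, cache).
// [[Rcpp::export]]
SEXP cpp_conv2d_fwd(NumericVector x, NumericVector w,
                    int stride, int pt, int pb, int pl, int pr,
                    int dil, int groups, bool keep_cache = false) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cing = wd[2], cout = wd[3];
  if (C != cing * groups && !(groups == C && cing == 1))
    stop("channel/group mismatch in convolution");
  const int Ho = conv_out_size(H, pt, pb, kh, dil, stride);
  const int Wo = conv_out_size(W, pl, pr, kw, dil, stride);
  if (Ho < 1 || Wo < 1) stop("convolution output collapsed to zero size");
  NumericVector out(Rcpp::no_init((R_xlen_t)Ho * Wo * cout * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  const int P = Ho * Wo;
  const double* xp = x.begin();
  double* op = out.begin();

  if (groups == 1) {
    const int K = kh * kw * C;
    arma::fmat Wm(K, cout);
    for (long long i = 0; i < (long long)K * cout; ++i) Wm.memptr()[i] = (float)w[i];
    // batched column matrix: column k holds all samples stacked, sample n
    // occupying rows [n*P, (n+1)*P)
    arma::fmat* colT = new arma::fmat((long long)N * P, K);
    for (int n = 0; n < N; ++n) {
      {
        const long long noff = (long long)n * H * W * C;
        for (int ci = 0; ci < C; ++ci) {
          const double* xc = xp + noff + (long long)ci * H * W;
          for (int kwi = 0; kwi < kw; ++kwi) {
            int wlo, whi;
            valid_range(Wo, stride, pl, kwi * dil, W, wlo, whi);
            for (int khi = 0; khi < kh; ++khi) {
              const int k = khi + kh * (kwi + kw * ci);
              float* dst = colT->colptr(k) + (long long)n * P;
              int hlo, hhi;
              valid_range(Ho, stride, pt, khi * dil, H, hlo, hhi);
              if (wlo > 0) std::memset(dst, 0, sizeof(float) * (size_t)wlo * Ho);
              if (whi < Wo)
                std::memset(dst + (long long)whi * Ho, 0,
                            sizeof(float) * (size_t)(Wo - whi) * Ho);
              for (int wo = wlo; wo < whi; ++wo) {
                const int iw = wo * stride - pl + kwi * dil;
                const double* xcol = xc + (long long)iw * H;
                float* dcol = dst + (long long)wo * Ho;
                for (int ho = 0; ho < hlo; ++ho) dcol[ho] = 0.0f;
                if (stride == 1) {
                  const double* xrun = xcol - pt + khi * dil;
                  for (int ho = hlo; ho < hhi; ++ho) dcol[ho] = (float)xrun[ho];
                } else {
                  for (int ho = hlo; ho < hhi; ++ho)
                    dcol[ho] = (float)xcol[ho * stride - pt + khi * dil];
                }
                for (int ho = hhi; ho < Ho; ++ho) dcol[ho] = 0.0f;
              }
            }
          }
        }
      }
    }
    arma::fmat y = (*colT) * Wm;                     // (N*P) x cout
    for (int n = 0; n < N; ++n) {
      double* on = op + (long long)n * P * cout;
      for (int co = 0; co < cout; ++co) {
        const float* yc = y.colptr(co) + (long long)n * P;
        double* oc = on + (long long)co * P;
        for (int p = 0; p < P; ++p) oc[p] = (double)yc[p];
      }
    }
    if (keep_cache) {
      XPtr<arma::fmat> ptr(colT, true);
      return List::create(_["y"] = out, _["cache"] = ptr);
    }
    delete colT;
    return out;
  } else {                                            // depthwise: groups == C, cout == C
    if (cout != C) stop("depthwise convolution requires Cout == Cin");
    std::memset(op, 0, sizeof(double) * (size_t)P * cout * N);
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + ((long long)n * C + c) * H * W;
        double* oc = op + ((long long)n * C + c) * P;
        for (int kwi = 0; kwi < kw; ++kwi) {
          for (int khi = 0; khi < kh; ++khi) {
            const double wv = w[khi + kh * (kwi + kw * (0 + 1 * c))];
            for (int wo = 0; wo < Wo; ++wo) {
              const int iw = wo * stride - pl + kwi * dil;
              if (iw < 0 || iw >= W) continue;
              const double* xcol = xc + (long long)iw * H;
              double* ocol = oc + (long long)wo * Ho;
              for (int ho = 0; ho < Ho; ++ho) {
                const int ih = ho * stride - pt + khi * dil;
                if (ih >= 0 && ih < H) ocol[ho] += wv * xcol[ih];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pt, int pb, int pl, int pr,
                    int dil, int groups, SEXP cache = R_NilValue,
                    bool need_dx = true) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cing = wd[2], cout = wd[3];
  IntegerVector dyd = dy.attr("dim");
  const int Ho = dyd[0], Wo = dyd[1];
  const int P = Ho * Wo;
  if (groups != 1) need_dx = true;   // depthwise path always produces dx
  NumericVector dx(need_dx ? (R_xlen_t)H * W * C * N : 0);
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)kh * kw * cing * cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, cing, cout);
  const double* xp = x.begin();
  const double* dyp = dy.begin();

  if (groups == 1) {
    const int K = kh * kw * C;
    arma::fmat Wm(K, cout);
    for (long long i = 0; i < (long long)K * cout; ++i) Wm.memptr()[i] = (float)w[i];
    arma::fmat* colT;
    bool own_col = false;
    if (cache != R_NilValue) {
      XPtr<arma::fmat> ptr(cache);
      colT = ptr.get();
    } else {
      own_col = true;
      colT = new arma::fmat((long long)N * P, K);
      arma::fmat tmp(P, K);
      for (int n = 0; n < N; ++n) {
        im2colT(xp, H, W, C, (long long)n * H * W * C, kh, kw, stride, pt, pl,
                dil, Ho, Wo, tmp);
        for (int k = 0; k < K; ++k)
          std::memcpy(colT->colptr(k) + (long long)n * P, tmp.colptr(k),
                      sizeof(float) * (size_t)P);
      }
    }
    arma::fmat dys((long long)N * P, cout);
    for (int n = 0; n < N; ++n) {
      const double* dyn = dyp + (long long)n * P * cout;
      for (int co = 0; co < cout; ++co) {
        float* dc = dys.colptr(co) + (long long)n * P;
        const double* sc = dyn + (long long)co * P;
        for (int p = 0; p < P; ++p) dc[p] = (float)sc[p];
      }
    }
    arma::fmat dWm = colT->t() * dys;                 // K x cout
    for (long long i = 0; i < (long long)K * cout; ++i) dw[i] = (double)dWm.memptr()[i];
    if (need_dx) {
      arma::fmat dcolT = dys * Wm.t();                // (N*P) x K
      for (int n = 0; n < N; ++n)
        col2imT_off(dcolT, (long long)n * P, dx.begin(), H, W, C,
                    (long long)n * H * W * C, kh, kw, stride, pt, pl, dil,
                    Ho, Wo);
    }
    if (own_col) delete colT;
  } else {
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + ((long long)n * C + c) * H * W;
        const double* dyc = dyp + ((long long)n * C + c) * P;
        double* dxc = dx.begin() + ((long long)n * C + c) * H * W;
        for (int kwi = 0; kwi < kw; ++kwi) {
          for (int khi = 0; khi < kh; ++khi) {
            const double wv = w[khi + kh * (kwi + kw * c)];
            double acc = 0.0;
            for (int wo = 0; wo < Wo; ++wo) {
              const int iw = wo * stride - pl + kwi * dil;
              if (iw < 0 || iw >= W) continue;
              const double* xcol = xc + (long long)iw * H;
              double* dxcol = dxc + (long long)iw * H;
              const double* dycol = dyc + (long long)wo * Ho;
              for (int ho = 0; ho < Ho; ++ho) {
                const int ih = ho * stride - pt + khi * dil;
                if (ih >= 0 && ih < H) {
                  acc += dycol[ho] * xcol[ih];
                  dxcol[ih] += wv * dycol[ho];
                }
              }
            }
            dw[khi + kh * (kwi + kw * c)] += acc;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Bilinear resampling with half-pixel centre alignment.
static inline void bilin_coeff(int i, int out, int in, int& i0, int& i1, double& a) {
  double s = ((double)i + 0.5) * (double)in / (double)out - 0.5;
  if (s < 0) s = 0;
  if (s > in - 1) s = in - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, in - 1);
  a = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  NumericVector out(Rcpp::no_init((R_xlen_t)Ho * Wo * C * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int i = 0; i < Ho; ++i) bilin_coeff(i, Ho, H, h0[i], h1[i], ah[i]);
  for (int j = 0; j < Wo; ++j) bilin_coeff(j, Wo, W, w0[j], w1[j], aw[j]);
  for (long long cn = 0; cn < (long long)C * N; ++cn) {
    const double* xs = x.begin() + cn * H * W;
    double* os = out.begin() + cn * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double* cL = xs + (long long)w0[j] * H;
      const double* cR = xs + (long long)w1[j] * H;
      const double b = aw[j];
      double* oc = os + (long long)j * Ho;
      for (int i = 0; i < Ho; ++i) {
        const double a = ah[i];
        const double top = (1 - b) * cL[h0[i]] + b * cR[h0[i]];
        const double bot = (1 - b) * cL[h1[i]] + b * cR[h1[i]];
        oc[i] = (1 - a) * top + a * bot;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector dy, int H, int W) {
  int Ho, Wo, C, N; get_dims4(dy, Ho, Wo, C, N);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int i = 0; i < Ho; ++i) bilin_coeff(i, Ho, H, h0[i], h1[i], ah[i]);
  for (int j = 0; j < Wo; ++j) bilin_coeff(j, Wo, W, w0[j], w1[j], aw[j]);
  for (long long cn = 0; cn < (long long)C * N; ++cn) {
    double* xs = dx.begin() + cn * H * W;
    const double* os = dy.begin() + cn * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double b = aw[j];
      double* cL = xs + (long long)w0[j] * H;
      double* cR = xs + (long long)w1[j] * H;
      const double* oc = os + (long long)j * Ho;
      for (int i = 0; i < Ho; ++i) {
        const double a = ah[i], g = oc[i];
        cL[h0[i]] += (1 - a) * (1 - b) * g;
        cR[h0[i]] += (1 - a) * b * g;
        cL[h1[i]] += a * (1 - b) * g;
        cR[h1[i]] += a * b * g;
      }
    }
  }
  return dx;
}

// Adaptive average pooling: output bin i over [floor(i*H/oh), ceil((i+1)*H/oh)).
static inline void bin_bounds(int i, int out, int in, int& lo, int& hi) {
  lo = (int)std::floor((double)i * in / out);
  hi = (int)std::ceil((double)(i + 1) * in / out);
}

// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool_fwd(NumericVector x, int oh, int ow) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  NumericVector out((R_xlen_t)oh * ow * C * N);
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  for (long long cn = 0; cn < (long long)C * N; ++cn) {
    const double* xs = x.begin() + cn * H * W;
    double* os = out.begin() + cn * oh * ow;
    for (int j = 0; j < ow; ++j) {
      int wlo, whi; bin_bounds(j, ow, W, wlo, whi);
      for (int i = 0; i < oh; ++i) {
        int hlo, hhi; bin_bounds(i, oh, H, hlo, hhi);
        double acc = 0.0;
        for (int w = wlo; w < whi; ++w)
          for (int h = hlo; h < hhi; ++h) acc += xs[(long long)w * H + h];
        os[(long long)j * oh + i] = acc / ((whi - wlo) * (hhi - hlo));
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool_bwd(NumericVector dy, int H, int W) {
  int oh, ow, C, N; get_dims4(dy, oh, ow, C, N);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (long long cn = 0; cn < (long long)C * N; ++cn) {
    double* xs = dx.begin() + cn * H * W;
    const double* os = dy.begin() + cn * oh * ow;
    for (int j = 0; j < ow; ++j) {
      int wlo, whi; bin_bounds(j, ow, W, wlo, whi);
      for (int i = 0; i < oh; ++i) {
        int hlo, hhi; bin_bounds(i, oh, H, hlo, hhi);
        const double g = os[(long long)j * oh + i] / ((whi - wlo) * (hhi - hlo));
        for (int w = wlo; w < whi; ++w)
          for (int h = hlo; h < hhi; ++h) xs[(long long)w * H + h] += g;
      }
    }
  }
  return dx;
}

// y = x * scale[c or (c,n)] + shift[same]; scale/shift of length C apply
// per channel across samples, of length C*N per channel per sample.
// [[Rcpp::export]]
NumericVector cpp_channel_affine(NumericVector x, NumericVector scale,
                                 NumericVector shift) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const long long HW = (long long)H * W;
  const bool per_sample = (scale.size() == (R_xlen_t)C * N);
  if (!per_sample && scale.size() != C) stop("scale length must be C or C*N");
  if (shift.size() != scale.size()) stop("scale/shift length mismatch");
  NumericVector out(Rcpp::no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const int k = per_sample ? (c + C * n) : c;
      const double s = scale[k], b = shift[k];
      const double* xs = xp + ((long long)n * C + c) * HW;
      double* os = op + ((long long)n * C + c) * HW;
      for (long long i = 0; i < HW; ++i) os[i] = xs[i] * s + b;
    }
  }
  return out;
}

// Fused in-place Adam update.  v, m, s are modified directly (the caller
// owns these buffers exclusively); b1t/b2t are the bias-correction terms
// 1 - beta^t.
// [[Rcpp::export]]
void cpp_adam_step(NumericVector v, NumericVector g, NumericVector m,
                   NumericVector s, double lr, double beta1, double beta2,
                   double eps, double b1t, double b2t) {
  const R_xlen_t n = v.size();
  if (g.size() != n || m.size() != n || s.size() != n)
    stop("adam buffer length mismatch");
  double* vp = v.begin();
  const double* gp = g.begin();
  double* mp = m.begin();
  double* sp = s.begin();
  const double ib1 = 1.0 / b1t, ib2 = 1.0 / b2t;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = gp[i];
    mp[i] = beta1 * mp[i] + (1 - beta1) * gi;
    sp[i] = beta2 * sp[i] + (1 - beta2) * gi * gi;
    vp[i] -= lr * (mp[i] * ib1) / (std::sqrt(sp[i] * ib2) + eps);
  }
}

// One-pass per-channel sum and sum of squares over H, W and N: 2 x C.
// [[Rcpp::export]]
NumericMatrix cpp_bn_reduce(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const long long HW = (long long)H * W;
  NumericMatrix out(2, C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((long long)n * C + c) * HW;
      double s = 0.0, ss = 0.0;
      for (long long i = 0; i < HW; ++i) {
        s += xs[i];
        ss += xs[i] * xs[i];
      }
      out(0, c) += s;
      out(1, c) += ss;
    }
  }
  return out;
}

// One-pass per-channel sums of a and of a*b over H, W and N: 2 x C.
// [[Rcpp::export]]
NumericMatrix cpp_bn_reduce2(NumericVector a, NumericVector b) {
  int H, W, C, N; get_dims4(a, H, W, C, N);
  if (b.size() != a.size()) stop("length mismatch");
  const long long HW = (long long)H * W;
  NumericMatrix out(2, C);
  const double* ap = a.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const long long off = ((long long)n * C + c) * HW;
      const double* as = ap + off;
      const double* bs = bp + off;
      double s = 0.0, sp = 0.0;
      for (long long i = 0; i < HW; ++i) {
        s += as[i];
        sp += as[i] * bs[i];
      }
      out(0, c) += s;
      out(1, c) += sp;
    }
  }
  return out;
}

// Per-channel-per-sample sums over the spatial plane: returns C x N matrix.
// [[Rcpp::export]]
NumericMatrix cpp_channel_sums(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const long long HW = (long long)H * W;
  NumericMatrix out(C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((long long)n * C + c) * HW;
      double acc = 0.0;
      for (long long i = 0; i < HW; ++i) acc += xs[i];
      out(c, n) = acc;
    }
  }
  return out;
}
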