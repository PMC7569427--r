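#include <Rcpp.h>
#include <vector>
#include <cstring>
#if defined(__x86_64__) || defined(__i386__)
#include <immintrin.h>
#define WANET_X86 1
#endif
using namespace Rcpp;

// Direct 3x3 (possibly atrous) convolution kernels on (N*H*W, C) feature-map
// matrices: one column per channel, rows scanned row-major within an image,
// images stacked. Weights are (9*Cin, Cout), kernel-tap-major row blocks.
//
// The kernels compute in single precision (the convention for CNN training;
// inputs and outputs remain double at the R interface). Each image is copied
// into a row-padded float scratch buffer so the inner loops carry no
// boundary branches. The hot loops exist twice: an AVX2/FMA micro-kernel
// holding a register tile of output channels x row positions, selected at
// runtime when the CPU supports it, and a portable fallback.

static inline bool use_avx2() {
#ifdef WANET_X86
  static const bool ok = __builtin_cpu_supports("avx2") &&
                         __builtin_cpu_supports("fma");
  return ok;
#else
  return false;
#endif
}

// Copy one image into a zero-padded float buffer ((W + 2d)-wide rows).
static inline void pad_image_f(const double* X, long P, int n, int H, int W,
                               int Cin, int d, std::vector<float>& Xpad) {
  const int Wp = W + 2 * d;
  std::fill(Xpad.begin(), Xpad.end(), 0.0f);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* src = X + (long)ci * P + (long)n * H * W;
    float* dst = Xpad.data() + (long)ci * H * Wp + d;
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j)
        dst[(long)i * Wp + j] = (float)src[(long)i * W + j];
  }
}

// Copy the whole batch into a zero-padded float buffer; channel-major,
// images stacked within a channel plane.
static inline void pad_batch_f(const double* X, int N, int H, int W,
                               int Cin, int d, std::vector<float>& Xpad) {
  const int Wp = W + 2 * d;
  const long P = (long)N * H * W;
  std::fill(Xpad.begin(), Xpad.end(), 0.0f);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* src = X + (long)ci * P;
    float* dst = Xpad.data() + (size_t)ci * N * H * Wp + d;
    for (long r = 0; r < (long)N * H; ++r)
      for (int j = 0; j < W; ++j)
        dst[r * Wp + j] = (float)src[r * W + j];
  }
}

// Pack a CB-wide output-channel block of the weights so the CB coefficients
// of one (tap, ci) pair are contiguous, in float.
static void pack_weights_f(const double* Wm, int Cin, int Cout, int CB,
                           std::vector<float>& wpack) {
  const int nblk = Cout / CB;
  wpack.assign((size_t)nblk * 9 * Cin * CB, 0.0f);
  for (int blk = 0; blk < nblk; ++blk) {
    float* wp = wpack.data() + (size_t)blk * 9 * Cin * CB;
    for (int tc = 0; tc < 9 * Cin; ++tc)
      for (int c = 0; c < CB; ++c)
        wp[(size_t)tc * CB + c] = (float)Wm[(size_t)(blk * CB + c) * 9 * Cin + tc];
  }
}

// Scalar float tile update used for all edge cases and the fallback path.
static inline void conv3_tile_generic(const float* Xpad, const double* Wm,
                                      int H, int W, int Wp, int Cin, int d,
                                      int i, int co0, int cb, int j0, int jb,
                                      const double* bias, float t[8][8]) {
  for (int c = 0; c < cb; ++c) {
    const float bc = bias ? (float)bias[co0 + c] : 0.0f;
    for (int jj = 0; jj < jb; ++jj) t[c][jj] = bc;
  }
  for (int a = -1; a <= 1; ++a) {
    const int si = i + a * d;
    if (si < 0 || si >= H) continue;
    const int trow = (a + 1) * 3;
    for (int ci = 0; ci < Cin; ++ci) {
      const float* xr = Xpad + ((long)ci * H + si) * Wp + j0;
      for (int c = 0; c < cb; ++c) {
        const double* wp = Wm + (long)(co0 + c) * 9 * Cin + ci;
        for (int tb = 0; tb < 3; ++tb) {
          const float w = (float)wp[(long)(trow + tb) * Cin];
          const float* xs = xr + tb * d;
          for (int jj = 0; jj < jb; ++jj) t[c][jj] += w * xs[jj];
        }
      }
    }
  }
}

#ifdef WANET_X86
// Micro-kernel: CB output channels x (8*JV) row positions per register tile.
template <int CB, int JV>
__attribute__((target("avx2,fma")))
static void conv3_core_avx2(const double* X, int N, int H, int W, int Cin,
                            const double* Wm, int Cout, const double* bias,
                            int d, bool relu, const double* add, double* Y) {
  const long P = (long)N * H * W;
  const int Wp = W + 2 * d;
  std::vector<float> Xpad((size_t)Cin * H * Wp + 8);
  std::vector<float> wpack;
  pack_weights_f(Wm, Cin, Cout, CB, wpack);
  const int nblk = Cout / CB;
  const int JW = 8 * JV;
  const int Wfull = W - (W % JW);
  const __m256 zero = _mm256_setzero_ps();
  for (int n = 0; n < N; ++n) {
    pad_image_f(X, P, n, H, W, Cin, d, Xpad);
    for (int i = 0; i < H; ++i) {
      const long orow = ((long)n * H + i) * W;
      for (int blk = 0; blk < nblk; ++blk) {
        const int co0 = blk * CB;
        const float* wpk = wpack.data() + (size_t)blk * 9 * Cin * CB;
        for (int j0 = 0; j0 < Wfull; j0 += JW) {
          __m256 acc[CB][JV];
          for (int c = 0; c < CB; ++c) {
            const __m256 b0 = bias ? _mm256_set1_ps((float)bias[co0 + c])
                                   : zero;
            for (int v = 0; v < JV; ++v) acc[c][v] = b0;
          }
          for (int a = -1; a <= 1; ++a) {
            const int si = i + a * d;
            if (si < 0 || si >= H) continue;
            const int trow = (a + 1) * 3;
            for (int ci = 0; ci < Cin; ++ci) {
              const float* xr = Xpad.data() + ((long)ci * H + si) * Wp + j0;
              const float* w8 = wpk + (size_t)(trow * Cin + ci) * CB;
              for (int tb = 0; tb < 3; ++tb, w8 += (size_t)Cin * CB) {
                __m256 xv[JV];
                for (int v = 0; v < JV; ++v)
                  xv[v] = _mm256_loadu_ps(xr + tb * d + 8 * v);
                for (int c = 0; c < CB; ++c) {
                  const __m256 wc = _mm256_broadcast_ss(w8 + c);
                  for (int v = 0; v < JV; ++v)
                    acc[c][v] = _mm256_fmadd_ps(wc, xv[v], acc[c][v]);
                }
              }
            }
          }
          for (int c = 0; c < CB; ++c) {
            double* yr = Y + orow + (long)(co0 + c) * P + j0;
            const double* ar = add ? add + orow + (long)(co0 + c) * P + j0
                                   : nullptr;
            for (int v = 0; v < JV; ++v) {
              const __m256 av = relu ? _mm256_max_ps(acc[c][v], zero)
                                     : acc[c][v];
              __m256d lo = _mm256_cvtps_pd(_mm256_castps256_ps128(av));
              __m256d hi = _mm256_cvtps_pd(_mm256_extractf128_ps(av, 1));
              if (ar) {
                lo = _mm256_add_pd(lo, _mm256_loadu_pd(ar + 8 * v));
                hi = _mm256_add_pd(hi, _mm256_loadu_pd(ar + 8 * v + 4));
              }
              _mm256_storeu_pd(yr + 8 * v, lo);
              _mm256_storeu_pd(yr + 8 * v + 4, hi);
            }
          }
        }
        for (int j0 = Wfull; j0 < W; j0 += 8) {  // masked row tail
          const int jb = (W - j0 < 8) ? (W - j0) : 8;
          __m256 acc[CB];
          for (int c = 0; c < CB; ++c)
            acc[c] = bias ? _mm256_set1_ps((float)bias[co0 + c]) : zero;
          for (int a = -1; a <= 1; ++a) {
            const int si = i + a * d;
            if (si < 0 || si >= H) continue;
            const int trow = (a + 1) * 3;
            for (int ci = 0; ci < Cin; ++ci) {
              const float* xr = Xpad.data() + ((long)ci * H + si) * Wp + j0;
              const float* w8 = wpk + (size_t)(trow * Cin + ci) * CB;
              for (int tb = 0; tb < 3; ++tb, w8 += (size_t)Cin * CB) {
                const __m256 xv = _mm256_loadu_ps(xr + tb * d);
                for (int c = 0; c < CB; ++c)
                  acc[c] = _mm256_fmadd_ps(_mm256_broadcast_ss(w8 + c), xv,
                                           acc[c]);
              }
            }
          }
          float buf[8];
          for (int c = 0; c < CB; ++c) {
            const __m256 av = relu ? _mm256_max_ps(acc[c], zero) : acc[c];
            _mm256_storeu_ps(buf, av);
            double* yr = Y + orow + (long)(co0 + c) * P + j0;
            const double* ar = add ? add + orow + (long)(co0 + c) * P + j0
                                   : nullptr;
            for (int jj = 0; jj < jb; ++jj)
              yr[jj] = (double)buf[jj] + (ar ? ar[jj] : 0.0);
          }
        }
      }
      const int corem = Cout % CB;
      if (corem) {  // channel tail
        const int co0 = Cout - corem;
        float t[8][8];
        for (int j0 = 0; j0 < W; j0 += 8) {
          const int jb = (W - j0 < 8) ? (W - j0) : 8;
          conv3_tile_generic(Xpad.data(), Wm, H, W, Wp, Cin, d, i, co0,
                             corem, j0, jb, bias, t);
          for (int c = 0; c < corem; ++c) {
            double* yr = Y + orow + (long)(co0 + c) * P + j0;
            const double* ar = add ? add + orow + (long)(co0 + c) * P + j0
                                   : nullptr;
            for (int jj = 0; jj < jb; ++jj) {
              const float v = (relu && t[c][jj] < 0) ? 0.0f : t[c][jj];
              yr[jj] = (double)v + (ar ? ar[jj] : 0.0);
            }
          }
        }
      }
    }
  }
}
#endif

static void conv3_core_fallback(const double* X, int N, int H, int W, int Cin,
                                const double* Wm, int Cout, const double* bias,
                                int d, bool relu, const double* add, double* Y) {
  const long P = (long)N * H * W;
  const int Wp = W + 2 * d;
  std::vector<float> Xpad((size_t)Cin * H * Wp + 8);
  for (int n = 0; n < N; ++n) {
    pad_image_f(X, P, n, H, W, Cin, d, Xpad);
    for (int i = 0; i < H; ++i) {
      const long orow = ((long)n * H + i) * W;
      for (int co0 = 0; co0 < Cout; co0 += 8) {
        const int cb = (Cout - co0 < 8) ? (Cout - co0) : 8;
        float t[8][8];
        for (int j0 = 0; j0 < W; j0 += 8) {
          const int jb = (W - j0 < 8) ? (W - j0) : 8;
          conv3_tile_generic(Xpad.data(), Wm, H, W, Wp, Cin, d, i, co0, cb,
                             j0, jb, bias, t);
          for (int c = 0; c < cb; ++c) {
            double* yr = Y + orow + (long)(co0 + c) * P + j0;
            const double* ar = add ? add + orow + (long)(co0 + c) * P + j0
                                   : nullptr;
            for (int jj = 0; jj < jb; ++jj) {
              const float v = (relu && t[c][jj] < 0) ? 0.0f : t[c][jj];
              yr[jj] = (double)v + (ar ? ar[jj] : 0.0);
            }
          }
        }
      }
    }
  }
}

static void conv3_core(const double* X, int N, int H, int W, int Cin,
                       const double* Wm, int Cout, const double* bias,
                       int d, bool relu, const double* add, double* Y) {
#ifdef WANET_X86
  if (use_avx2()) {
    if (Cout % 4 == 0) {
      if (W % 16 == 0)
        conv3_core_avx2<4, 2>(X, N, H, W, Cin, Wm, Cout, bias, d, relu, add, Y);
      else
        conv3_core_avx2<4, 1>(X, N, H, W, Cin, Wm, Cout, bias, d, relu, add, Y);
    } else if (Cout % 2 == 0) {
      conv3_core_avx2<2, 2>(X, N, H, W, Cin, Wm, Cout, bias, d, relu, add, Y);
    } else {
      conv3_core_avx2<1, 2>(X, N, H, W, Cin, Wm, Cout, bias, d, relu, add, Y);
    }
    return;
  }
#endif
  conv3_core_fallback(X, N, H, W, Cin, Wm, Cout, bias, d, relu, add, Y);
}

// ---------------------------------------------------------------------------
// weight-gradient core
// dW[tap(a,b)*Cin + ci, co] = sum_p dY[p, co] * X[p + (a*W+b)*d, ci]
// ---------------------------------------------------------------------------

#ifdef WANET_X86
__attribute__((target("avx2,fma")))
static void conv3_dw_avx2(const double* X, const double* dY, int N, int H,
                          int W, int Cin, int Cout, int d, double* dW) {
  const long P = (long)N * H * W;
  const int Wp = W + 2 * d;
  std::vector<float> Xpad((size_t)Cin * N * H * Wp + 8);
  pad_batch_f(X, N, H, W, Cin, d, Xpad);
  std::vector<float> dYf((size_t)P * Cout + 8, 0.0f);
  for (long k = 0; k < (long)P * Cout; ++k) dYf[k] = (float)dY[k];
  const int Wfull = W - (W % 8);
  alignas(32) int mi[8];
  const int jbt = W - Wfull;
  for (int k = 0; k < 8; ++k) mi[k] = (k < jbt) ? -1 : 0;
  const __m256i msk = _mm256_load_si256((const __m256i*)mi);
  for (int co0 = 0; co0 < Cout; co0 += 4) {
    const int cb = (Cout - co0 < 4) ? (Cout - co0) : 4;
    const float* dyp0 = dYf.data() + (long)(co0 + 0) * P;
    const float* dyp1 = dYf.data() + (long)(co0 + (cb > 1 ? 1 : 0)) * P;
    const float* dyp2 = dYf.data() + (long)(co0 + (cb > 2 ? 2 : 0)) * P;
    const float* dyp3 = dYf.data() + (long)(co0 + (cb > 3 ? 3 : 0)) * P;
    for (int ci = 0; ci < Cin; ++ci) {
      const float* xpl = Xpad.data() + (size_t)ci * N * H * Wp;
      for (int a = -1; a <= 1; ++a) {
        const int trow = (a + 1) * 3;
        __m256 s[4][3];
        for (int c = 0; c < 4; ++c)
          for (int tb = 0; tb < 3; ++tb) s[c][tb] = _mm256_setzero_ps();
        for (int n = 0; n < N; ++n) {
          const int i0 = (a < 0) ? d : 0;          // rows whose tap row exists
          const int i1 = (a > 0) ? H - d : H;
          for (int i = i0; i < i1; ++i) {
            const long orow = ((long)n * H + i) * W;
            const float* xr = xpl + ((long)n * H + i + a * d) * Wp;
            const float* dy0 = dyp0 + orow;
            const float* dy1 = dyp1 + orow;
            const float* dy2 = dyp2 + orow;
            const float* dy3 = dyp3 + orow;
            for (int j = 0; j < Wfull; j += 8) {
              const __m256 x0 = _mm256_loadu_ps(xr + j);
              const __m256 x1 = _mm256_loadu_ps(xr + j + d);
              const __m256 x2 = _mm256_loadu_ps(xr + j + 2 * d);
              const __m256 v0 = _mm256_loadu_ps(dy0 + j);
              s[0][0] = _mm256_fmadd_ps(v0, x0, s[0][0]);
              s[0][1] = _mm256_fmadd_ps(v0, x1, s[0][1]);
              s[0][2] = _mm256_fmadd_ps(v0, x2, s[0][2]);
              const __m256 v1 = _mm256_loadu_ps(dy1 + j);
              s[1][0] = _mm256_fmadd_ps(v1, x0, s[1][0]);
              s[1][1] = _mm256_fmadd_ps(v1, x1, s[1][1]);
              s[1][2] = _mm256_fmadd_ps(v1, x2, s[1][2]);
              const __m256 v2 = _mm256_loadu_ps(dy2 + j);
              s[2][0] = _mm256_fmadd_ps(v2, x0, s[2][0]);
              s[2][1] = _mm256_fmadd_ps(v2, x1, s[2][1]);
              s[2][2] = _mm256_fmadd_ps(v2, x2, s[2][2]);
              const __m256 v3 = _mm256_loadu_ps(dy3 + j);
              s[3][0] = _mm256_fmadd_ps(v3, x0, s[3][0]);
              s[3][1] = _mm256_fmadd_ps(v3, x1, s[3][1]);
              s[3][2] = _mm256_fmadd_ps(v3, x2, s[3][2]);
            }
            if (jbt) {
              const int j = Wfull;
              const __m256 x0 = _mm256_loadu_ps(xr + j);
              const __m256 x1 = _mm256_loadu_ps(xr + j + d);
              const __m256 x2 = _mm256_loadu_ps(xr + j + 2 * d);
              const __m256 v0 = _mm256_maskload_ps(dy0 + j, msk);
              s[0][0] = _mm256_fmadd_ps(v0, x0, s[0][0]);
              s[0][1] = _mm256_fmadd_ps(v0, x1, s[0][1]);
              s[0][2] = _mm256_fmadd_ps(v0, x2, s[0][2]);
              const __m256 v1 = _mm256_maskload_ps(dy1 + j, msk);
              s[1][0] = _mm256_fmadd_ps(v1, x0, s[1][0]);
              s[1][1] = _mm256_fmadd_ps(v1, x1, s[1][1]);
              s[1][2] = _mm256_fmadd_ps(v1, x2, s[1][2]);
              const __m256 v2 = _mm256_maskload_ps(dy2 + j, msk);
              s[2][0] = _mm256_fmadd_ps(v2, x0, s[2][0]);
              s[2][1] = _mm256_fmadd_ps(v2, x1, s[2][1]);
              s[2][2] = _mm256_fmadd_ps(v2, x2, s[2][2]);
              const __m256 v3 = _mm256_maskload_ps(dy3 + j, msk);
              s[3][0] = _mm256_fmadd_ps(v3, x0, s[3][0]);
              s[3][1] = _mm256_fmadd_ps(v3, x1, s[3][1]);
              s[3][2] = _mm256_fmadd_ps(v3, x2, s[3][2]);
            }
          }
        }
        float buf[8];
        for (int c = 0; c < cb; ++c) {
          double* dwc = dW + (long)(co0 + c) * 9 * Cin;
          for (int tb = 0; tb < 3; ++tb) {
            _mm256_storeu_ps(buf, s[c][tb]);
            double acc = 0.0;
            for (int k = 0; k < 8; ++k) acc += buf[k];
            dwc[(long)(trow + tb) * Cin + ci] += acc;
          }
        }
      }
    }
  }
}
#endif

static void conv3_dw_fallback(const double* X, const double* dY, int N, int H,
                              int W, int Cin, int Cout, int d, double* dW) {
  const long P = (long)N * H * W;
  const int Wp = W + 2 * d;
  std::vector<float> Xpad((size_t)Cin * H * Wp + 8);
  for (int n = 0; n < N; ++n) {
    pad_image_f(X, P, n, H, W, Cin, d, Xpad);
    for (int i = 0; i < H; ++i) {
      const long orow = ((long)n * H + i) * W;
      for (int a = -1; a <= 1; ++a) {
        const int si = i + a * d;
        if (si < 0 || si >= H) continue;
        const int trow = (a + 1) * 3;
        for (int co = 0; co < Cout; ++co) {
          const double* dyr = dY + orow + (long)co * P;
          double* dwc = dW + (long)co * 9 * Cin;
          for (int ci = 0; ci < Cin; ++ci) {
            const float* xr = Xpad.data() + ((long)ci * H + si) * Wp;
            float s0 = 0.0f, s1 = 0.0f, s2 = 0.0f;
            for (int j = 0; j < W; ++j) {
              const float dv = (float)dyr[j];
              s0 += dv * xr[j];
              s1 += dv * xr[j + d];
              s2 += dv * xr[j + 2 * d];
            }
            dwc[(long)(trow + 0) * Cin + ci] += s0;
            dwc[(long)(trow + 1) * Cin + ci] += s1;
            dwc[(long)(trow + 2) * Cin + ci] += s2;
          }
        }
      }
    }
  }
}

static void conv3_dw_core(const double* X, const double* dY, int N, int H,
                          int W, int Cin, int Cout, int d, double* dW) {
#ifdef WANET_X86
  if (use_avx2()) {
    conv3_dw_avx2(X, dY, N, H, W, Cin, Cout, d, dW);
    return;
  }
#endif
  conv3_dw_fallback(X, dY, N, H, W, Cin, Cout, d, dW);
}

// ---------------------------------------------------------------------------
// R entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(const NumericMatrix& X, int N, int H, int W,
                            const NumericMatrix& Wm, const NumericVector& b,
                            int d, bool relu = false,
                            Nullable<NumericMatrix> add = R_NilValue) {
  const int Cin = X.ncol(), Cout = Wm.ncol();
  if (X.nrow() != (long)N * H * W) stop("conv3: row count != N*H*W");
  if (Wm.nrow() != 9 * Cin) stop("conv3: weight rows != 9*Cin");
  if (b.size() != 0 && b.size() != Cout) stop("conv3: bias length != Cout");
  NumericMatrix Y(X.nrow(), Cout);
  const double* ap = nullptr;
  NumericMatrix am;
  if (add.isNotNull()) {
    am = add.get();
    if (am.nrow() != X.nrow() || am.ncol() != Cout)
      stop("conv3: addend shape mismatch");
    ap = &am[0];
  }
  conv3_core(&X[0], N, H, W, Cin, &Wm[0], Cout,
             b.size() ? &b[0] : nullptr, d, relu, ap, &Y[0]);
  return Y;
}

// Gradient w.r.t. the input: a direct convolution of dY with the
// tap-reversed, transposed kernel.
// [[Rcpp::export]]
NumericMatrix cpp_conv3_dx(const NumericMatrix& dY, int N, int H, int W,
                           const NumericMatrix& Wm, int d,
                           Nullable<NumericMatrix> add = R_NilValue) {
  const int Cout = dY.ncol();
  const int Cin = Wm.nrow() / 9;
  if (Wm.ncol() != Cout) stop("conv3_dx: weight cols != Cout");
  std::vector<double> Wb((size_t)9 * Cout * Cin);
  for (int t = 0; t < 9; ++t)
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co)
        Wb[(size_t)ci * 9 * Cout + (8 - t) * Cout + co] =
          Wm[(size_t)co * 9 * Cin + (size_t)t * Cin + ci];
  NumericMatrix dX(dY.nrow(), Cin);
  const double* ap = nullptr;
  NumericMatrix am;
  if (add.isNotNull()) {
    am = add.get();
    if (am.nrow() != dY.nrow() || am.ncol() != Cin)
      stop("conv3_dx: addend shape mismatch");
    ap = &am[0];
  }
  conv3_core(&dY[0], N, H, W, Cout, Wb.data(), Cin, nullptr, d, false, ap, &dX[0]);
  return dX;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_dw(const NumericMatrix& X, const NumericMatrix& dY,
                           int N, int H, int W, int d) {
  const int Cin = X.ncol(), Cout = dY.ncol();
  NumericMatrix dW(9 * Cin, Cout);
  conv3_dw_core(&X[0], &dY[0], N, H, W, Cin, Cout, d, &dW[0]);
  return dW;
}

// 2x2 max pooling (stride 2) with argmax rows for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool2(const NumericMatrix& X, int N, int H, int W) {
  const int C = X.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const long Po = (long)N * Ho * Wo;
  NumericMatrix Y(Po, C);
  IntegerMatrix AM(Po, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    int* am = &AM(0, c);
    for (int n = 0; n < N; ++n) {
      for (int io = 0; io < Ho; ++io) {
        const long r0 = ((long)n * H + 2 * io) * W;
        const long r1 = r0 + W;
        long q = ((long)n * Ho + io) * Wo;
        for (int jo = 0; jo < Wo; ++jo, ++q) {
          const long p00 = r0 + 2 * jo, p01 = p00 + 1;
          const long p10 = r1 + 2 * jo, p11 = p10 + 1;
          long best = p00; double bv = x[p00];
          if (x[p01] > bv) { bv = x[p01]; best = p01; }
          if (x[p10] > bv) { bv = x[p10]; best = p10; }
          if (x[p11] > bv) { bv = x[p11]; best = p11; }
          y[q] = bv;
          am[q] = (int)(best + 1);  // 1-based row index
        }
      }
    }
  }
  return List::create(Named("Y") = Y, Named("argmax") = AM,
                      Named("in_rows") = (double)((long)N * H * W));
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool2_bwd(const NumericMatrix& dY, const IntegerMatrix& AM,
                               int in_rows) {
  const int C = dY.ncol();
  NumericMatrix dX(in_rows, C);
  for (int c = 0; c < C; ++c) {
    const double* g = &dY(0, c);
    const int* am = &AM(0, c);
    double* o = &dX(0, c);
    const long n = dY.nrow();
    for (long q = 0; q < n; ++q) o[am[q] - 1] += g[q];
  }
  return dX;
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export]]
NumericMatrix cpp_upsample2(const NumericMatrix& X, int N, int H, int W) {
  const int C = X.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  NumericMatrix Y((long)N * Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    for (int n = 0; n < N; ++n)
      for (int io = 0; io < Ho; ++io) {
        const double* xr = x + ((long)n * H + io / 2) * W;
        double* yr = y + ((long)n * Ho + io) * Wo;
        for (int j = 0; j < W; ++j) { yr[2 * j] = xr[j]; yr[2 * j + 1] = xr[j]; }
      }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample2_bwd(const NumericMatrix& dY, int N, int H, int W) {
  const int C = dY.ncol();
  NumericMatrix dX((long)N * H * W, C);
  const int Ho = 2 * H, Wo = 2 * W;
  for (int c = 0; c < C; ++c) {
    const double* g = &dY(0, c);
    double* o = &dX(0, c);
    for (int n = 0; n < N; ++n)
      for (int io = 0; io < Ho; ++io) {
        const double* gr = g + ((long)n * Ho + io) * Wo;
        double* orow = o + ((long)n * H + io / 2) * W;
        for (int j = 0; j < W; ++j)
          orow[j] += gr[2 * j] + gr[2 * j + 1];
      }
  }
  return dX;
}

// Elementwise helpers kept in C++ because they sit on the per-step hot path.

// [[Rcpp::export]]
NumericMatrix cpp_relu(const NumericMatrix& X) {
  NumericMatrix Y(X.nrow(), X.ncol());
  const long n = (long)X.nrow() * X.ncol();
  const double* x = &X[0];
  double* y = &Y[0];
  for (long i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return Y;
}

// Gradient of ReLU: propagate dY where the stored activation is positive.
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(const NumericMatrix& dY, const NumericMatrix& act) {
  if (dY.nrow() != act.nrow() || dY.ncol() != act.ncol())
    stop("relu_bwd: shape mismatch");
  NumericMatrix dX(dY.nrow(), dY.ncol());
  const long n = (long)dY.nrow() * dY.ncol();
  const double* g = &dY[0];
  const double* v = &act[0];
  double* o = &dX[0];
  for (long i = 0; i < n; ++i) o[i] = v[i] > 0 ? g[i] : 0.0;
  return dX;
}

// [[Rcpp::export]]
NumericMatrix cpp_leaky_relu(const NumericMatrix& X, double a) {
  NumericMatrix Y(X.nrow(), X.ncol());
  const long n = (long)X.nrow() * X.ncol();
  const double* x = &X[0];
  double* y = &Y[0];
  for (long i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : a * x[i];
  return Y;
}
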