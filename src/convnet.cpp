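// Minimal CNN primitives: 2-D convolution ("same" zero padding) and 2x2
// max-pooling, forward and backward. Tensors use R's column-major layout
// with dimensions (H, W, C, N); kernels (K, K, Cin, Cout) with K odd.
#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static NumericVector alloc4d(int d1, int d2, int d3, int d4) {
  NumericVector v((R_xlen_t)d1 * d2 * d3 * d4);
  v.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  return v;
}

static IntegerVector alloc4d_int(int d1, int d2, int d3, int d4) {
  IntegerVector v((R_xlen_t)d1 * d2 * d3 * d4);
  v.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  return v;
}

// Direct "same"-padding convolution. Input planes are copied once per
// sample into a zero-padded single-precision buffer, so every inner loop
// runs branch-free over the full column height and vectorises cleanly;
// work proceeds one output column at a time through a stack buffer held in
// L1. Single precision is ample for stochastic gradient training; the R
// interface stays double.

static void pad_planes(const double* x, int H, int W, int C, int P,
                       std::vector<float>& buf) {
  const int Hp = H + 2 * P, Wp = W + 2 * P;
  buf.assign((size_t)C * Hp * Wp, 0.0f);
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)c * H * W;
    float* out = buf.data() + (size_t)c * Hp * Wp;
    for (int j = 0; j < W; ++j) {
      const double* src = plane + (size_t)j * H;
      float* dst = out + (size_t)(j + P) * Hp + P;
      for (int i = 0; i < H; ++i) dst[i] = (float)src[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(const NumericVector& x, const NumericVector& w,
                                 const NumericVector& b, bool relu = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int HW = H * W, P = K / 2, Hp = H + 2 * P, HWp = Hp * (W + 2 * P);

  std::vector<float> wf(w.size());
  for (R_xlen_t k = 0; k < w.size(); ++k) wf[k] = (float)w[k];
  std::vector<float> xpad, ycol(H);

  NumericVector y = alloc4d(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    pad_planes(x.begin() + (size_t)n * HW * Cin, H, W, Cin, P, xpad);
    double* yn = y.begin() + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* yplane = yn + (size_t)co * HW;
      const float bc = (float)b[co];
      for (int j = 0; j < W; ++j) {
        std::fill(ycol.begin(), ycol.end(), bc);
        for (int c = 0; c < Cin; ++c) {
          const float* xplane = xpad.data() + (size_t)c * HWp;
          for (int kj = 0; kj < K; ++kj) {
            const float* xcol = xplane + (size_t)(j + kj) * Hp;
            for (int ki = 0; ki < K; ++ki) {
              const float wv =
                wf[ki + (size_t)K * kj + (size_t)K * K * c + (size_t)K * K * Cin * co];
              const float* src = xcol + ki;
              for (int i = 0; i < H; ++i) ycol[i] += wv * src[i];
            }
          }
        }
        double* dst = yplane + (size_t)j * H;
        if (relu) {
          for (int i = 0; i < H; ++i) dst[i] = ycol[i] > 0.0f ? (double)ycol[i] : 0.0;
        } else {
          for (int i = 0; i < H; ++i) dst[i] = (double)ycol[i];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(const NumericVector& x, const NumericVector& w,
                         const NumericVector& dy, bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int HW = H * W, P = K / 2, Hp = H + 2 * P, HWp = Hp * (W + 2 * P);

  std::vector<float> wf(w.size());
  for (R_xlen_t k = 0; k < w.size(); ++k) wf[k] = (float)w[k];
  std::vector<float> xpad, dypad, dxcol(H);

  NumericVector dx = alloc4d(H, W, Cin, N);
  NumericVector dw = alloc4d(K, K, Cin, Cout);
  NumericVector db(Cout);

  for (int n = 0; n < N; ++n) {
    pad_planes(x.begin() + (size_t)n * HW * Cin, H, W, Cin, P, xpad);
    pad_planes(dy.begin() + (size_t)n * HW * Cout, H, W, Cout, P, dypad);
    double* dxn = dx.begin() + (size_t)n * HW * Cin;
    const double* dyn = dy.begin() + (size_t)n * HW * Cout;

    // weight and bias gradients: dy columns stream once per output channel
    for (int co = 0; co < Cout; ++co) {
      const double* dyplane = dyn + (size_t)co * HW;
      double acc = 0.0;
      for (int p = 0; p < HW; ++p) acc += dyplane[p];
      db[co] += acc;
      const float* dypadplane = dypad.data() + (size_t)co * HWp;
      for (int j = 0; j < W; ++j) {
        const float* dycol = dypadplane + (size_t)(j + P) * Hp + P;
        for (int c = 0; c < Cin; ++c) {
          const float* xplane = xpad.data() + (size_t)c * HWp;
          for (int kj = 0; kj < K; ++kj) {
            const float* xcol = xplane + (size_t)(j + kj) * Hp;
            for (int ki = 0; ki < K; ++ki) {
              const float* srcx = xcol + ki;
              float wacc = 0.0f;
              for (int i = 0; i < H; ++i) wacc += srcx[i] * dycol[i];
              dw[ki + (size_t)K * kj + (size_t)K * K * c + (size_t)K * K * Cin * co]
                += (double)wacc;
            }
          }
        }
      }
    }

    // input gradient: full correlation of padded dy with the flipped kernel
    if (need_dx) {
      for (int c = 0; c < Cin; ++c) {
        double* dxplane = dxn + (size_t)c * HW;
        for (int sj = 0; sj < W; ++sj) {
          std::fill(dxcol.begin(), dxcol.end(), 0.0f);
          for (int co = 0; co < Cout; ++co) {
            const float* dyplane = dypad.data() + (size_t)co * HWp;
            for (int kj = 0; kj < K; ++kj) {
              const float* dycol = dyplane + (size_t)(sj + 2 * P - kj) * Hp;
              for (int ki = 0; ki < K; ++ki) {
                const float wv =
                  wf[ki + (size_t)K * kj + (size_t)K * K * c + (size_t)K * K * Cin * co];
                const float* src = dycol + (2 * P - ki);
                for (int i = 0; i < H; ++i) dxcol[i] += wv * src[i];
              }
            }
          }
          double* out = dxplane + (size_t)sj * H;
          for (int i = 0; i < H; ++i) out[i] = (double)dxcol[i];
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// 2x2 max pooling, stride 2, floor semantics on odd sizes. Returns pooled
// values and the 0-based linear argmax index into x (ties -> first element
// in column-major order, deterministic).
// [[Rcpp::export]]
List maxpool2_forward_cpp(const NumericVector& x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4d(Ho, Wo, C, N);
  IntegerVector idx = alloc4d_int(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          size_t best = base + (size_t)(2 * jo) * H + 2 * io;
          double bv = xp[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int k = 0; k < 3; ++k) {
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          }
          yp[o] = bv;
          ip[o] = (int)best;
          ++o;
        }
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward_cpp(const IntegerVector& idx,
                                    const NumericVector& dy,
                                    const IntegerVector& xdim) {
  NumericVector dx = alloc4d(xdim[0], xdim[1], xdim[2], xdim[3]);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  const R_xlen_t M = dy.size();
  for (R_xlen_t k = 0; k < M; ++k) dxp[ip[k]] += dyp[k];
  return dx;
}

// dz masked by the ReLU derivative at pre-activation z
// [[Rcpp::export]]
NumericVector relu_backward_cpp(const NumericVector& dz, const NumericVector& z) {
  NumericVector out = clone(dz);
  double* p = out.begin();
  const double* zp = z.begin();
  const R_xlen_t M = out.size();
  for (R_xlen_t k = 0; k < M; ++k) if (zp[k] <= 0) p[k] = 0;
  return out;
}
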