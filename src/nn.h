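#ifndef TIBIASEG_NN_H
#define TIBIASEG_NN_H

#include <RcppArmadillo.h>
#include <random>

// Activation batches are held as arma::fcube(H*W, C, N): pixel index
// p = h + H*w (column-major within a slice), one matrix slice per sample.
// This layout is bit-compatible with an R array of dim c(H, W, C, N).

using arma::fmat;
using arma::fcube;
using arma::frowvec;

inline int convOut(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

// K(po, r) with r = ky + k*kx + k*k*c ; po = ho + Ho*wo
inline void im2col(const fmat& Xs, int H, int W, int C, int k, int stride,
                   int pad, fmat& K) {
  const int Ho = convOut(H, k, stride, pad);
  const int Wo = convOut(W, k, stride, pad);
  if (stride == 1) {
    // fast path: every (c, kx, ky, wo) run is a contiguous memcpy
    K.set_size(Ho * Wo, k * k * C);
    for (int c = 0; c < C; ++c) {
      const float* x = Xs.colptr(c);
      for (int kx = 0; kx < k; ++kx) {
        for (int ky = 0; ky < k; ++ky) {
          float* kc = K.colptr(ky + k * kx + k * k * c);
          const int hoLo = std::max(0, pad - ky);
          const int hoHi = std::min(Ho, H + pad - ky);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo - pad + kx;
            float* kcol = kc + (arma::uword)Ho * wo;
            if (wi < 0 || wi >= W) {
              std::memset(kcol, 0, Ho * sizeof(float));
              continue;
            }
            const float* xcol = x + (arma::uword)H * wi;
            if (hoLo > 0) std::memset(kcol, 0, hoLo * sizeof(float));
            std::memcpy(kcol + hoLo, xcol + hoLo + ky - pad,
                        (hoHi - hoLo) * sizeof(float));
            if (hoHi < Ho) std::memset(kcol + hoHi, 0, (Ho - hoHi) * sizeof(float));
          }
        }
      }
    }
    return;
  }
  K.zeros(Ho * Wo, k * k * C);
  for (int c = 0; c < C; ++c) {
    const float* x = Xs.colptr(c);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        float* kc = K.colptr(ky + k * kx + k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kx;
          if (wi < 0 || wi >= W) continue;
          float* kcol = kc + (arma::uword)Ho * wo;
          const float* xcol = x + (arma::uword)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ky;
            if (hi < 0 || hi >= H) continue;
            kcol[ho] = xcol[hi];
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
inline void col2im(const fmat& K, int H, int W, int C, int k, int stride,
                   int pad, fmat& dXs) {
  const int Ho = convOut(H, k, stride, pad);
  const int Wo = convOut(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    float* dx = dXs.colptr(c);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const float* kc = K.colptr(ky + k * kx + k * k * c);
        if (stride == 1) {
          const int hoLo = std::max(0, pad - ky);
          const int hoHi = std::min(Ho, H + pad - ky);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo - pad + kx;
            if (wi < 0 || wi >= W) continue;
            const float* kcol = kc + (arma::uword)Ho * wo;
            float* dxcol = dx + (arma::uword)H * wi + ky - pad;
            for (int ho = hoLo; ho < hoHi; ++ho) dxcol[ho] += kcol[ho];
          }
          continue;
        }
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kx;
          if (wi < 0 || wi >= W) continue;
          const float* kcol = kc + (arma::uword)Ho * wo;
          float* dxcol = dx + (arma::uword)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ky;
            if (hi < 0 || hi >= H) continue;
            dxcol[hi] += kcol[ho];
          }
        }
      }
    }
  }
}

struct Conv {
  fmat A;            // (k*k*Cin, Cout)
  frowvec b;         // (Cout)
  fmat mA, vA; frowvec mb, vb;   // Adam moments
  int k = 3, stride = 1, pad = 1, Cin = 0, Cout = 0;
  fmat gA; frowvec gb;           // gradients
  void init(int k_, int s_, int p_, int ci, int co, std::mt19937& rng) {
    k = k_; stride = s_; pad = p_; Cin = ci; Cout = co;
    const float sd = std::sqrt(2.0f / (k * k * Cin));
    std::normal_distribution<float> nd(0.0f, sd);
    A.set_size(k * k * Cin, Cout);
    for (arma::uword i = 0; i < A.n_elem; ++i) A(i) = nd(rng);
    b.zeros(Cout);
    mA.zeros(arma::size(A)); vA.zeros(arma::size(A));
    mb.zeros(Cout); vb.zeros(Cout);
  }
  void zeroGrad() { gA.zeros(arma::size(A)); gb.zeros(1, Cout); }
};

// Stack the im2col matrices of all samples row-wise so each conv is a
// single GEMM over the whole batch (small per-sample GEMMs are
// overhead-dominated at these channel counts).
inline void im2colBatch(const fcube& X, int H, int W, int C, int k,
                        int stride, int pad, fmat& K, int Ho, int Wo) {
  const int N = X.n_slices;
  K.set_size((arma::uword)Ho * Wo * N, (arma::uword)k * k * C);
  fmat Kn;
  for (int n = 0; n < N; ++n) {
    im2col(X.slice(n), H, W, C, k, stride, pad, Kn);
    K.rows((arma::uword)Ho * Wo * n, (arma::uword)Ho * Wo * (n + 1) - 1) = Kn;
  }
}

// y(p,c,n): conv of X(H,W) -> (Ho,Wo)
inline fcube convFwd(const Conv& L, const fcube& X, int H, int W,
                     int& Ho, int& Wo, fmat* Kbuf = nullptr) {
  Ho = convOut(H, L.k, L.stride, L.pad);
  Wo = convOut(W, L.k, L.stride, L.pad);
  const int N = X.n_slices;
  fcube Y(Ho * Wo, L.Cout, N);
  fmat K;
  im2colBatch(X, H, W, L.Cin, L.k, L.stride, L.pad, K, Ho, Wo);
  fmat Yall = K * L.A;
  for (int n = 0; n < N; ++n) {
    Y.slice(n) = Yall.rows((arma::uword)Ho * Wo * n,
                           (arma::uword)Ho * Wo * (n + 1) - 1);
    Y.slice(n).each_row() += L.b;
  }
  (void)Kbuf;
  return Y;
}

// accumulate parameter grads; return dX if wantDX
inline fcube convBwd(Conv& L, const fcube& X, const fcube& dY, int H, int W,
                     bool wantDX) {
  const int N = X.n_slices;
  const int Ho = convOut(H, L.k, L.stride, L.pad);
  const int Wo = convOut(W, L.k, L.stride, L.pad);
  fcube dX;
  if (wantDX) dX.zeros(H * W, L.Cin, N);
  fmat K;
  im2colBatch(X, H, W, L.Cin, L.k, L.stride, L.pad, K, Ho, Wo);
  fmat dYall((arma::uword)Ho * Wo * N, L.Cout);
  for (int n = 0; n < N; ++n) {
    dYall.rows((arma::uword)Ho * Wo * n, (arma::uword)Ho * Wo * (n + 1) - 1) =
      dY.slice(n);
    L.gb += arma::sum(dY.slice(n), 0);
  }
  L.gA += K.t() * dYall;
  if (wantDX) {
    fmat dKall = dYall * L.A.t();
    for (int n = 0; n < N; ++n) {
      fmat dKn = dKall.rows((arma::uword)Ho * Wo * n,
                            (arma::uword)Ho * Wo * (n + 1) - 1);
      col2im(dKn, H, W, L.Cin, L.k, L.stride, L.pad, dX.slice(n));
    }
  }
  return dX;
}

struct BN {
  frowvec g, b, rm, rv;
  frowvec mg, vg, mb, vb;
  frowvec gg, gb;
  frowvec mean, invstd;          // batch stats cached for backward
  float eps = 1e-5f, mom = 0.1f;
  void init(int C) {
    g.ones(C); b.zeros(C); rm.zeros(C); rv.ones(C);
    mg.zeros(C); vg.zeros(C); mb.zeros(C); vb.zeros(C);
  }
  void zeroGrad() { gg.zeros(1, g.n_cols); gb.zeros(1, g.n_cols); }
};

inline fcube bnFwd(BN& L, const fcube& X, bool train) {
  const int C = X.n_cols, N = X.n_slices;
  const arma::uword P = X.n_rows;
  fcube Y(arma::size(X));
  if (train) {
    L.mean.zeros(C); L.invstd.zeros(C);
    const double Nt = (double)P * N;
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (int n = 0; n < N; ++n) s += arma::accu(X.slice(n).col(c));
      const double mu = s / Nt;
      double v = 0;
      for (int n = 0; n < N; ++n) {
        const float* x = X.slice(n).colptr(c);
        for (arma::uword p = 0; p < P; ++p) { double d = x[p] - mu; v += d * d; }
      }
      const double var = v / Nt;
      L.mean(c) = (float)mu;
      L.invstd(c) = (float)(1.0 / std::sqrt(var + L.eps));
      L.rm(c) = (1 - L.mom) * L.rm(c) + L.mom * (float)mu;
      const double varU = Nt > 1 ? v / (Nt - 1) : var;
      L.rv(c) = (1 - L.mom) * L.rv(c) + L.mom * (float)varU;
    }
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c)
        Y.slice(n).col(c) = (X.slice(n).col(c) - L.mean(c)) * (L.invstd(c) * L.g(c)) + L.b(c);
  } else {
    for (int c = 0; c < C; ++c) {
      const float is = 1.0f / std::sqrt(L.rv(c) + L.eps);
      for (int n = 0; n < N; ++n)
        Y.slice(n).col(c) = (X.slice(n).col(c) - L.rm(c)) * (is * L.g(c)) + L.b(c);
    }
  }
  return Y;
}

inline fcube bnBwd(BN& L, const fcube& X, const fcube& dY) {
  const int C = X.n_cols, N = X.n_slices;
  const arma::uword P = X.n_rows;
  const double Nt = (double)P * N;
  fcube dX(arma::size(X));
  for (int c = 0; c < C; ++c) {
    double sdy = 0, sdyxh = 0;
    for (int n = 0; n < N; ++n) {
      const float* x = X.slice(n).colptr(c);
      const float* dy = dY.slice(n).colptr(c);
      for (arma::uword p = 0; p < P; ++p) {
        const double xh = (x[p] - L.mean(c)) * L.invstd(c);
        sdy += dy[p];
        sdyxh += dy[p] * xh;
      }
    }
    L.gb(c) += (float)sdy;
    L.gg(c) += (float)sdyxh;
    const double gi = L.g(c) * L.invstd(c);
    for (int n = 0; n < N; ++n) {
      const float* x = X.slice(n).colptr(c);
      const float* dy = dY.slice(n).colptr(c);
      float* dx = dX.slice(n).colptr(c);
      for (arma::uword p = 0; p < P; ++p) {
        const double xh = (x[p] - L.mean(c)) * L.invstd(c);
        dx[p] = (float)(gi * (dy[p] - sdy / Nt - xh * sdyxh / Nt));
      }
    }
  }
  return dX;
}

inline void reluInplace(fcube& X) {
  X.transform([](float v) { return v > 0 ? v : 0.0f; });
}

inline fcube reluBwd(const fcube& out, const fcube& dY) {
  fcube dX = dY;
  for (arma::uword i = 0; i < dX.n_elem; ++i)
    if (out(i) <= 0) dX(i) = 0;
  return dX;
}

// 2x2 max pooling, stride 2; argmax indices stored as pixel index
inline fcube pool2Fwd(const fcube& X, int H, int W, arma::ucube& amax) {
  const int Ho = H / 2, Wo = W / 2, C = X.n_cols, N = X.n_slices;
  fcube Y(Ho * Wo, C, N);
  amax.set_size(Ho * Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* x = X.slice(n).colptr(c);
      float* y = Y.slice(n).colptr(c);
      arma::uword* am = amax.slice(n).colptr(c);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = 2 * ho, w0 = 2 * wo;
          arma::uword best = h0 + (arma::uword)H * w0;
          float bv = x[best];
          const int cand[3][2] = {{h0 + 1, w0}, {h0, w0 + 1}, {h0 + 1, w0 + 1}};
          for (auto& cd : cand) {
            arma::uword ix = cd[0] + (arma::uword)H * cd[1];
            if (x[ix] > bv) { bv = x[ix]; best = ix; }
          }
          y[ho + (arma::uword)Ho * wo] = bv;
          am[ho + (arma::uword)Ho * wo] = best;
        }
    }
  return Y;
}

inline fcube pool2Bwd(const fcube& dY, const arma::ucube& amax, int H, int W) {
  const int C = dY.n_cols, N = dY.n_slices;
  fcube dX(H * W, C, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* dy = dY.slice(n).colptr(c);
      const arma::uword* am = amax.slice(n).colptr(c);
      float* dx = dX.slice(n).colptr(c);
      for (arma::uword p = 0; p < dY.n_rows; ++p) dx[am[p]] += dy[p];
    }
  return dX;
}

// bilinear x2 upsampling, align_corners = false convention:
// src = (out + 0.5)/2 - 0.5, clamped.
struct Up2Map {
  std::vector<int> i0, i1; std::vector<float> t;
  void build(int Hin) {
    const int Ho = 2 * Hin;
    i0.resize(Ho); i1.resize(Ho); t.resize(Ho);
    for (int o = 0; o < Ho; ++o) {
      const float s = (o + 0.5f) / 2.0f - 0.5f;
      int a = (int)std::floor(s);
      float tt = s - a;
      if (a < 0) { a = 0; tt = 0; }
      int b = a + 1;
      if (b > Hin - 1) { b = Hin - 1; tt = 0; }
      i0[o] = a; i1[o] = b; t[o] = tt;
    }
  }
};

inline fcube up2Fwd(const fcube& X, int H, int W) {
  const int Ho = 2 * H, Wo = 2 * W, C = X.n_cols, N = X.n_slices;
  Up2Map mh, mw; mh.build(H); mw.build(W);
  fcube Y(Ho * Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* x = X.slice(n).colptr(c);
      float* y = Y.slice(n).colptr(c);
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = mw.i0[wo], w1 = mw.i1[wo];
        const float tw = mw.t[wo];
        const float* x0 = x + (arma::uword)H * w0;
        const float* x1 = x + (arma::uword)H * w1;
        float* yc = y + (arma::uword)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = mh.i0[ho], h1 = mh.i1[ho];
          const float th = mh.t[ho];
          const float a = x0[h0] * (1 - th) + x0[h1] * th;
          const float b = x1[h0] * (1 - th) + x1[h1] * th;
          yc[ho] = a * (1 - tw) + b * tw;
        }
      }
    }
  return Y;
}

inline fcube up2Bwd(const fcube& dY, int H, int W) {
  const int Ho = 2 * H, Wo = 2 * W, C = dY.n_cols, N = dY.n_slices;
  Up2Map mh, mw; mh.build(H); mw.build(W);
  fcube dX(H * W, C, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      float* dx = dX.slice(n).colptr(c);
      const float* dy = dY.slice(n).colptr(c);
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = mw.i0[wo], w1 = mw.i1[wo];
        const float tw = mw.t[wo];
        const float* dyc = dy + (arma::uword)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = mh.i0[ho], h1 = mh.i1[ho];
          const float th = mh.t[ho];
          const float d = dyc[ho];
          dx[h0 + (arma::uword)H * w0] += d * (1 - th) * (1 - tw);
          dx[h1 + (arma::uword)H * w0] += d * th * (1 - tw);
          dx[h0 + (arma::uword)H * w1] += d * (1 - th) * tw;
          dx[h1 + (arma::uword)H * w1] += d * th * tw;
        }
      }
    }
  return dX;
}

inline void sigmoidInplace(fcube& X) {
  X.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
}

#endif
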