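// Single-precision training engine for the U-Net (+ optional sum-product
// refinement head). The R implementation is the reference; this engine
// replicates its training math in float with persistent workspaces, because
// the training loop is memory-bandwidth bound. Weights are imported from the
// R-side initializers and exported back to the R model structures, so
// inference and evaluation always run through the reference code.

#include <RcppArmadillo.h>
#include <vector>
#include <string>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

struct Adam { fmat mw, vw; fvec mb, vb; };

struct ConvBlock {
  int k = 3, cin = 0, cout = 0;
  fmat w; fvec b, gamma, beta, rm, rv;
  Adam aw, ag; // ag: moments for gamma/beta stored in mb/vb of a second Adam
  Adam agb;
  // caches
  fmat x;            // input (HW x cin*B)
  fvec mu, invstd;   // batch statistics (xhat is recomputed from the output)
  bool has_bn = true;
  double slope = 0.1;
};

static void adam_update(fmat& p, const fmat& g, fmat& m, fmat& v, float lr,
                        float b1, float b2, float eps, float bc1, float bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}
static void adam_update(fvec& p, const fvec& g, fvec& m, fvec& v, float lr,
                        float b1, float b2, float eps, float bc1, float bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

// im2col stripe (float), layout (H*nox) x (k*k*C) from feature matrix
// (HW x C*B) column block of image b.
static void im2col_stripe(const fmat& x, int b, int H, int W, int C, int k,
                          int ox0, int nox, fmat& col) {
  const int p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const float* xc = x.colptr(b * C + c);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        float* dst = col.colptr(ki + kj * k + c * k * k);
        for (int oi = 0; oi < nox; ++oi) {
          const int ix = ox0 + oi + kj - p;
          float* d = dst + (size_t)oi * H;
          if (ix < 0 || ix >= W) { std::fill(d, d + H, 0.f); continue; }
          const float* src = xc + (size_t)ix * H;
          const int lo = std::max(0, p - ki), hi = std::min(H, H + p - ki);
          if (lo > 0) std::fill(d, d + lo, 0.f);
          if (hi < H) std::fill(d + hi, d + H, 0.f);
          if (hi > lo) std::copy(src + lo + ki - p, src + hi + ki - p, d + lo);
        }
      }
  }
}

struct Shape { int H, W; };

struct Trainer {
  // config
  int levels, width, L, H, W, B;
  double slope, outScale;
  int finalK;
  // unet blocks: enc(levels*2), dec(levels*2), final conv (no bn)
  std::vector<ConvBlock> enc, dec;
  ConvBlock fin;
  // activations per stage (HW x C*B), persistent
  std::vector<fmat> acts;   // generic scratch per layer
  // gaffa
  bool hasGaffa = false;
  int P = 0, df = 1, ksf = 1, kh = 0, kwd = 0, wh = 0, ww = 0;
  double gbeta_ = 5.0, geps = 1e-6;
  std::vector<int> pi, pj;
  fmat kst;   // (kd1*kd2) x P stored kernels
  fmat bst;   // (wh*ww) x P biases
  fvec ggamma, gbeta2, grm, grv;
  fmat gxhat; fvec ginvstd;  // heatmap batch-norm caches
  Adam akst, abst; fvec mgg, vgg, mgb, vgb;
  int t = 0; // adam step
  double lambda = NA_REAL;
  // resize taps
  struct Taps { std::vector<int> idx; std::vector<float> w; int out, in; };
  Taps tapDownR, tapDownC, tapUpR, tapUpC, tapKR, tapKC;
  std::vector<fmat> Ms;  // per-pair Toeplitz matrices, built in fwd, reused in bwd
};

static Trainer::Taps makeTaps(int outN, int inN) {
  // pixel-area bicubic (Catmull-Rom), clamped: mirrors the R resizeTaps
  Trainer::Taps t; t.out = outN; t.in = inN;
  t.idx.resize(outN * 4); t.w.resize(outN * 4);
  auto kern = [](double x) {
    const double a = -0.5, ax = std::fabs(x);
    if (ax <= 1) return (a + 2) * ax * ax * ax - (a + 3) * ax * ax + 1;
    if (ax < 2) return a * ax * ax * ax - 5 * a * ax * ax + 8 * a * ax - 4 * a;
    return 0.0;
  };
  for (int o = 0; o < outN; ++o) {
    double pos = (o + 0.5) * ((double)inN / outN) - 0.5;
    int base = (int)std::floor(pos);
    double ws[4], sum = 0;
    for (int tt = 0; tt < 4; ++tt) { ws[tt] = kern(pos - (base - 1 + tt)); sum += ws[tt]; }
    for (int tt = 0; tt < 4; ++tt) {
      t.idx[4 * o + tt] = std::min(std::max(base - 1 + tt, 0), inN - 1);
      t.w[4 * o + tt] = (float)(ws[tt] / sum);
    }
  }
  return t;
}

// separable 4-tap resize of one (Hi x Wi) channel into (Ho x Wo); tmp is
// (Ho x Wi) scratch.
static void resize1(const float* x, float* y, const Trainer::Taps& tr,
                    const Trainer::Taps& tc, fmat& tmp) {
  const int Hi = tr.in, Ho = tr.out, Wi = tc.in, Wo = tc.out;
  for (int c = 0; c < Wi; ++c) {
    const float* col = x + (size_t)c * Hi;
    float* dst = tmp.colptr(c);
    for (int o = 0; o < Ho; ++o) {
      const int* id = &tr.idx[4 * o]; const float* wv = &tr.w[4 * o];
      dst[o] = wv[0] * col[id[0]] + wv[1] * col[id[1]] +
               wv[2] * col[id[2]] + wv[3] * col[id[3]];
    }
  }
  for (int oc = 0; oc < Wo; ++oc) {
    const int* id = &tc.idx[4 * oc]; const float* wv = &tc.w[4 * oc];
    const float* c0 = tmp.colptr(id[0]); const float* c1 = tmp.colptr(id[1]);
    const float* c2 = tmp.colptr(id[2]); const float* c3 = tmp.colptr(id[3]);
    float* out = y + (size_t)oc * Ho;
    for (int o = 0; o < Ho; ++o)
      out[o] = wv[0] * c0[o] + wv[1] * c1[o] + wv[2] * c2[o] + wv[3] * c3[o];
  }
}

// adjoint of resize1: scatter gy (Ho x Wo) into gx (Hi x Wi), accumulating.
static void resize1_adj(const float* gy, float* gx, const Trainer::Taps& tr,
                        const Trainer::Taps& tc, fmat& tmp) {
  const int Hi = tr.in, Ho = tr.out, Wi = tc.in, Wo = tc.out;
  tmp.zeros(); // (Ho x Wi)
  for (int oc = 0; oc < Wo; ++oc) {
    const int* id = &tc.idx[4 * oc]; const float* wv = &tc.w[4 * oc];
    const float* g = gy + (size_t)oc * Ho;
    for (int tt = 0; tt < 4; ++tt) {
      float* dst = tmp.colptr(id[tt]);
      const float w = wv[tt];
      for (int o = 0; o < Ho; ++o) dst[o] += w * g[o];
    }
  }
  for (int c = 0; c < Wi; ++c) {
    const float* src = tmp.colptr(c);
    float* dst = gx + (size_t)c * Hi;
    for (int o = 0; o < Ho; ++o) {
      const int* id = &tr.idx[4 * o]; const float* wv = &tr.w[4 * o];
      const float v = src[o];
      for (int tt = 0; tt < 4; ++tt) dst[id[tt]] += wv[tt] * v;
    }
  }
}

static inline float softplusb(float x, float beta) {
  const float bx = beta * x;
  return (bx > 0 ? x : 0.f) + log1pf(expf(-std::fabs(bx))) / beta;
}
static inline float sigmoidb(float x, float beta) {
  return 1.f / (1.f + expf(-beta * x));
}

// conv forward y = conv(x) for all images; x (HW x cin*B), y (HW x cout*B).
// Per-channel sums/squares for batch norm are accumulated stripe-by-stripe
// while the results are still cache-resident.
static void conv_fwd(const fmat& x, fmat& y, const ConvBlock& c, Shape s, int B,
                     fmat& colbuf, arma::vec* sum = nullptr,
                     arma::vec* sumsq = nullptr) {
  const int K = c.k * c.k * c.cin;
  const int NB = std::max(4, std::min(64, 65536 / std::max(1, s.H * K / 8)));
  if ((int)colbuf.n_rows < s.H * NB || (int)colbuf.n_cols < K)
    colbuf.set_size(s.H * NB, K);
  if (sum) { sum->zeros(c.cout); sumsq->zeros(c.cout); }
  for (int b = 0; b < B; ++b) {
    fmat yb(y.colptr(b * c.cout), (size_t)s.H * s.W, c.cout, false, true);
    for (int ox0 = 0; ox0 < s.W; ox0 += NB) {
      const int nox = std::min(NB, s.W - ox0);
      im2col_stripe(x, b, s.H, s.W, c.cin, c.k, ox0, nox, colbuf);
      const size_t r0 = (size_t)ox0 * s.H, r1 = (size_t)(ox0 + nox) * s.H - 1;
      yb.rows(r0, r1) =
        colbuf.submat(0, 0, (size_t)nox * s.H - 1, K - 1) * c.w;
      if (sum)
        for (int ch = 0; ch < c.cout; ++ch) {
          const float* p = yb.colptr(ch) + r0;
          const float bb = c.b[ch];
          double sm = 0, s2 = 0;
          const size_t n = r1 - r0 + 1;
          for (size_t k = 0; k < n; ++k) {
            const double v = p[k] + bb;
            sm += v; s2 += v * v;
          }
          (*sum)[ch] += sm; (*sumsq)[ch] += s2;
        }
    }
    for (int ch = 0; ch < c.cout; ++ch) yb.col(ch) += c.b[ch];
  }
}

// conv backward: gw/gb accumulate; gx written (zeroed first) unless null.
static void conv_bwd(const fmat& x, const fmat& gy, const ConvBlock& c, Shape s,
                     int B, fmat& gw, fvec& gb, fmat* gx, fmat& colbuf,
                     fmat& gcolbuf) {
  const int K = c.k * c.k * c.cin;
  const int p = (c.k - 1) / 2;
  const int NB = std::max(4, std::min(64, 65536 / std::max(1, s.H * K / 8)));
  if ((int)colbuf.n_rows < s.H * NB || (int)colbuf.n_cols < K)
    colbuf.set_size(s.H * NB, K);
  if ((int)gcolbuf.n_rows < s.H * NB || (int)gcolbuf.n_cols < K)
    gcolbuf.set_size(s.H * NB, K);
  gw.zeros(K, c.cout); gb.zeros(c.cout);
  if (gx) gx->zeros((size_t)s.H * s.W, c.cin * B);
  for (int b = 0; b < B; ++b) {
    const fmat gyb(const_cast<float*>(gy.colptr(b * c.cout)),
                   (size_t)s.H * s.W, c.cout, false, true);
    for (int ox0 = 0; ox0 < s.W; ox0 += NB) {
      const int nox = std::min(NB, s.W - ox0);
      im2col_stripe(x, b, s.H, s.W, c.cin, c.k, ox0, nox, colbuf);
      fmat gys = gyb.rows((size_t)ox0 * s.H, (size_t)(ox0 + nox) * s.H - 1);
      gw += colbuf.submat(0, 0, (size_t)nox * s.H - 1, K - 1).t() * gys;
      gb += arma::sum(gys, 0).t();
      if (!gx) continue;
      gcolbuf.submat(0, 0, (size_t)nox * s.H - 1, K - 1) = gys * c.w.t();
      for (int ch = 0; ch < c.cin; ++ch) {
        float* xc = gx->colptr(b * c.cin + ch);
        for (int kj = 0; kj < c.k; ++kj)
          for (int ki = 0; ki < c.k; ++ki) {
            const float* src = gcolbuf.colptr(ki + kj * c.k + ch * c.k * c.k);
            for (int oi = 0; oi < nox; ++oi) {
              const int ix = ox0 + oi + kj - p;
              if (ix < 0 || ix >= s.W) continue;
              float* dc = xc + (size_t)ix * s.H;
              const float* sc = src + (size_t)oi * s.H;
              const int lo = std::max(0, p - ki), hi = std::min(s.H, s.H + p - ki);
              for (int oy = lo; oy < hi; ++oy) dc[oy + ki - p] += sc[oy];
            }
          }
      }
    }
  }
}

// fused bn + leaky activation, in place on z; batch statistics either
// precomputed during the convolution (sum/sumsq) or computed here.
static void bnact_fwd(ConvBlock& c, fmat& z, Shape s, int B, bool training,
                      const arma::vec* sum = nullptr,
                      const arma::vec* sumsq = nullptr) {
  const size_t HW = (size_t)s.H * s.W;
  const float mom = 0.1f, eps = training ? 1e-5f : 1e-8f;
  c.mu.set_size(c.cout);
  c.invstd.set_size(c.cout);
  for (int ch = 0; ch < c.cout; ++ch) {
    float mu, var;
    if (training) {
      double sm = 0, s2 = 0;
      if (sum) { sm = (*sum)[ch]; s2 = (*sumsq)[ch]; }
      else
        for (int b = 0; b < B; ++b) {
          const float* p = z.colptr(b * c.cout + ch);
          for (size_t k = 0; k < HW; ++k) { sm += p[k]; s2 += (double)p[k] * p[k]; }
        }
      const double n = (double)HW * B;
      mu = (float)(sm / n);
      var = std::max((float)(s2 / n - (sm / n) * (sm / n)), 0.f);
      c.rm[ch] = (1 - mom) * c.rm[ch] + mom * mu;
      c.rv[ch] = (1 - mom) * c.rv[ch] + mom * var;
    } else { mu = c.rm[ch]; var = c.rv[ch]; }
    const float is = 1.f / std::sqrt(var + eps);
    c.mu[ch] = mu; c.invstd[ch] = is;
    const float ga = c.gamma[ch], be = c.beta[ch], sl = (float)c.slope;
    for (int b = 0; b < B; ++b) {
      float* y = z.colptr(b * c.cout + ch);
      for (size_t k = 0; k < HW; ++k) {
        const float v = ga * ((y[k] - mu) * is) + be;
        y[k] = v < 0 ? sl * v : v;
      }
    }
  }
}

// backward through activation+bn, in place on g; xhat is recomputed from the
// cached post-activation output y (the next layer's input), so no extra
// buffer is written in the forward pass.
static void bnact_bwd(ConvBlock& c, fmat& g, const fmat& y, Shape s, int B,
                      bool training, fvec& ggamma, fvec& gbeta) {
  const size_t HW = (size_t)s.H * s.W;
  const double n = (double)HW * B;
  ggamma.zeros(c.cout); gbeta.zeros(c.cout);
  for (int ch = 0; ch < c.cout; ++ch) {
    float ga = c.gamma[ch];
    if (std::fabs(ga) < 1e-6f) ga = ga < 0 ? -1e-6f : 1e-6f;
    const float be = c.beta[ch], is = c.invstd[ch], sl = (float)c.slope;
    const float inv_sl = 1.f / sl, inv_ga = 1.f / ga;
    double s1 = 0, s2 = 0, sgg = 0, sgb = 0;
    for (int b = 0; b < B; ++b) {
      float* gg = g.colptr(b * c.cout + ch);
      const float* yy = y.colptr(b * c.cout + ch);
      for (size_t k = 0; k < HW; ++k) {
        const float yv = yy[k];
        const float ybn = yv < 0 ? yv * inv_sl : yv;
        const float xh = (ybn - be) * inv_ga;
        const float gact = yv < 0 ? gg[k] * sl : gg[k];
        gg[k] = gact;
        sgg += (double)gact * xh;
        sgb += gact;
        s2 += (double)gact * xh;
      }
    }
    s1 = sgb * ga; s2 = sgg * ga;
    ggamma[ch] = (float)sgg; gbeta[ch] = (float)sgb;
    const float m1 = (float)(s1 / n), m2 = (float)(s2 / n);
    for (int b = 0; b < B; ++b) {
      float* gg = g.colptr(b * c.cout + ch);
      const float* yy = y.colptr(b * c.cout + ch);
      for (size_t k = 0; k < HW; ++k) {
        const float yv = yy[k];
        const float ybn = yv < 0 ? yv * inv_sl : yv;
        const float xh = (ybn - be) * inv_ga;
        const float gxh = gg[k] * ga;
        gg[k] = training ? is * (gxh - m1 - xh * m2) : is * gxh;
      }
    }
  }
}

static void avgpool_fwd(const fmat& x, fmat& y, Shape s, int C, int B) {
  const int Ho = s.H / 2, Wo = s.W / 2;
  for (int cb = 0; cb < C * B; ++cb) {
    const float* xs = x.colptr(cb);
    float* ys = y.colptr(cb);
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy) {
        const float* p = xs + (size_t)(2 * ox) * s.H + 2 * oy;
        ys[oy + (size_t)ox * Ho] = 0.25f * (p[0] + p[1] + p[s.H] + p[s.H + 1]);
      }
  }
}
static void avgpool_bwd(const fmat& g, fmat& gx, Shape s, int C, int B) {
  const int Ho = s.H / 2, Wo = s.W / 2;
  for (int cb = 0; cb < C * B; ++cb) {
    const float* gs = g.colptr(cb);
    float* xs = gx.colptr(cb);
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy) {
        const float v = 0.25f * gs[oy + (size_t)ox * Ho];
        float* p = xs + (size_t)(2 * ox) * s.H + 2 * oy;
        p[0] += v; p[1] += v; p[s.H] += v; p[s.H + 1] += v;
      }
  }
}

static void up2_taps_f(int Ho, int Hi, std::vector<int>& i0, std::vector<int>& i1,
                       std::vector<float>& w1) {
  i0.resize(Ho); i1.resize(Ho); w1.resize(Ho);
  for (int o = 0; o < Ho; ++o) {
    double pos = (o + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(pos);
    w1[o] = (float)(pos - lo);
    i0[o] = std::min(std::max(lo, 0), Hi - 1);
    i1[o] = std::min(std::max(lo + 1, 0), Hi - 1);
  }
}
static void up2_fwd(const fmat& x, fmat& y, Shape si, int C, int B) {
  const int Ho = 2 * si.H, Wo = 2 * si.W;
  std::vector<int> r0, r1, c0, c1; std::vector<float> rw, cw;
  up2_taps_f(Ho, si.H, r0, r1, rw);
  up2_taps_f(Wo, si.W, c0, c1, cw);
  for (int cb = 0; cb < C * B; ++cb) {
    const float* xs = x.colptr(cb);
    float* ys = y.colptr(cb);
    for (int ox = 0; ox < Wo; ++ox) {
      const float* a0 = xs + (size_t)c0[ox] * si.H;
      const float* a1 = xs + (size_t)c1[ox] * si.H;
      const float wc = cw[ox];
      for (int oy = 0; oy < Ho; ++oy) {
        const float wr = rw[oy];
        ys[oy + (size_t)ox * Ho] =
          (1 - wr) * ((1 - wc) * a0[r0[oy]] + wc * a1[r0[oy]]) +
          wr * ((1 - wc) * a0[r1[oy]] + wc * a1[r1[oy]]);
      }
    }
  }
}
static void up2_bwd(const fmat& g, fmat& gx, Shape si, int C, int B) {
  const int Ho = 2 * si.H, Wo = 2 * si.W;
  std::vector<int> r0, r1, c0, c1; std::vector<float> rw, cw;
  up2_taps_f(Ho, si.H, r0, r1, rw);
  up2_taps_f(Wo, si.W, c0, c1, cw);
  gx.zeros();
  for (int cb = 0; cb < C * B; ++cb) {
    const float* gs = g.colptr(cb);
    float* xs = gx.colptr(cb);
    for (int ox = 0; ox < Wo; ++ox) {
      float* a0 = xs + (size_t)c0[ox] * si.H;
      float* a1 = xs + (size_t)c1[ox] * si.H;
      const float wc = cw[ox];
      for (int oy = 0; oy < Ho; ++oy) {
        const float v = gs[oy + (size_t)ox * Ho];
        const float wr = rw[oy];
        a0[r0[oy]] += (1 - wr) * (1 - wc) * v;
        a1[r0[oy]] += (1 - wr) * wc * v;
        a0[r1[oy]] += wr * (1 - wc) * v;
        a1[r1[oy]] += wr * wc * v;
      }
    }
  }
}

static fmat importMat(SEXP m) {
  NumericMatrix nm(m);
  fmat out(nm.nrow(), nm.ncol());
  for (size_t k = 0; k < out.n_elem; ++k) out[k] = (float)nm[k];
  return out;
}
static fvec importVec(SEXP v) {
  NumericVector nv(v);
  fvec out(nv.size());
  for (int k = 0; k < nv.size(); ++k) out[k] = (float)nv[k];
  return out;
}

} // namespace

// ------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_trainer_create(List unetParams, List unetCfg, Nullable<List> gaffaState,
                        int H, int W, int B) {
  Trainer* tr = new Trainer();
  tr->levels = as<int>(unetCfg["levels"]);
  tr->width = as<int>(unetCfg["width"]);
  tr->L = as<int>(unetCfg["outChannels"]);
  tr->slope = as<double>(unetCfg["leakySlope"]);
  tr->outScale = as<double>(unetCfg["outputScale"]);
  tr->finalK = as<int>(unetCfg["finalKernel"]);
  tr->H = H; tr->W = W; tr->B = B;
  const int wdt = tr->width;
  auto loadBlock = [&](std::string nm, int cin, int cout) {
    ConvBlock c;
    List p = unetParams[nm];
    c.k = 3; c.cin = cin; c.cout = cout; c.slope = tr->slope;
    c.w = importMat(p["w"]); c.b = importVec(p["b"]);
    c.gamma = importVec(p["gamma"]); c.beta = importVec(p["beta"]);
    c.rm.zeros(cout); c.rv.ones(cout);
    c.aw.mw.zeros(c.w.n_rows, c.w.n_cols); c.aw.vw.zeros(c.w.n_rows, c.w.n_cols);
    c.aw.mb.zeros(cout); c.aw.vb.zeros(cout);
    c.agb.mb.zeros(cout); c.agb.vb.zeros(cout);
    c.ag.mb.zeros(cout); c.ag.vb.zeros(cout);
    return c;
  };
  for (int lv = 1; lv <= tr->levels; ++lv) {
    tr->enc.push_back(loadBlock("enc" + std::to_string(lv) + "_c1",
                                lv == 1 ? 1 : wdt, wdt));
    tr->enc.push_back(loadBlock("enc" + std::to_string(lv) + "_c2", wdt, wdt));
  }
  for (int lv = 1; lv <= tr->levels; ++lv) {
    tr->dec.push_back(loadBlock("dec" + std::to_string(lv) + "_c1", 2 * wdt, wdt));
    tr->dec.push_back(loadBlock("dec" + std::to_string(lv) + "_c2", wdt, wdt));
  }
  {
    List p = unetParams["final"];
    tr->fin.k = tr->finalK; tr->fin.cin = wdt; tr->fin.cout = tr->L;
    tr->fin.has_bn = false;
    tr->fin.w = importMat(p["w"]); tr->fin.b = importVec(p["b"]);
    tr->fin.aw.mw.zeros(tr->fin.w.n_rows, tr->fin.w.n_cols);
    tr->fin.aw.vw.zeros(tr->fin.w.n_rows, tr->fin.w.n_cols);
    tr->fin.aw.mb.zeros(tr->L); tr->fin.aw.vb.zeros(tr->L);
  }
  if (gaffaState.isNotNull()) {
    List gs(gaffaState);
    List gp = gs["params"];
    List cfg = gs["cfg"];
    tr->hasGaffa = true;
    tr->df = as<int>(cfg["downFactor"]);
    tr->ksf = as<int>(cfg["kernelStoreFactor"]);
    tr->gbeta_ = as<double>(cfg["beta"]);
    tr->geps = as<double>(cfg["epsilon"]);
    tr->wh = H / tr->df; tr->ww = W / tr->df;
    List kern = gp["kernels"], bias = gp["biases"];
    tr->P = kern.size();
    NumericMatrix k0 = kern[0];
    tr->kh = k0.nrow(); tr->kwd = k0.ncol();
    tr->kst.set_size((size_t)tr->kh * tr->kwd, tr->P);
    tr->bst.set_size((size_t)tr->wh * tr->ww, tr->P);
    for (int p = 0; p < tr->P; ++p) {
      NumericMatrix km = kern[p];
      NumericMatrix bm = bias[p];
      for (size_t k = 0; k < tr->kst.n_rows; ++k) tr->kst(k, p) = (float)km[k];
      for (size_t k = 0; k < tr->bst.n_rows; ++k) tr->bst(k, p) = (float)bm[k];
    }
    DataFrame pairs = as<DataFrame>(gs["pairs"]);
    IntegerVector ii = pairs["i"], jj = pairs["j"];
    tr->pi.assign(ii.begin(), ii.end());
    tr->pj.assign(jj.begin(), jj.end());
    tr->ggamma = importVec(gp["bnGamma"]);
    tr->gbeta2 = importVec(gp["bnBeta"]);
    tr->grm.zeros(tr->L); tr->grv.ones(tr->L);
    tr->akst.mw.zeros(tr->kst.n_rows, tr->P); tr->akst.vw.zeros(tr->kst.n_rows, tr->P);
    tr->abst.mw.zeros(tr->bst.n_rows, tr->P); tr->abst.vw.zeros(tr->bst.n_rows, tr->P);
    tr->mgg.zeros(tr->L); tr->vgg.zeros(tr->L);
    tr->mgb.zeros(tr->L); tr->vgb.zeros(tr->L);
    tr->tapDownR = makeTaps(tr->wh, H); tr->tapDownC = makeTaps(tr->ww, W);
    tr->tapUpR = makeTaps(H, tr->wh); tr->tapUpC = makeTaps(W, tr->ww);
    tr->tapKR = makeTaps(2 * tr->wh, tr->kh); tr->tapKC = makeTaps(2 * tr->ww, tr->kwd);
  }
  XPtr<Trainer> ptr(tr, true);
  return ptr;
}

// Message convolution via a per-pair float Toeplitz matrix (cache resident
// for the working resolutions used here) so BLAS carries the batch:
//   M(n, m) = K[c + n - m],  out = M * Hbatch.
static void msg_toeplitz_f(const float* K, int h, int w, fmat& M) {
  const int N = h * w;
  M.set_size(N, N);
  for (int mx = 0; mx < w; ++mx)
    for (int my = 0; my < h; ++my) {
      float* mcol = M.colptr(my + mx * h);
      for (int nx = 0; nx < w; ++nx) {
        const float* kc = K + (size_t)(w + nx - mx) * 2 * h + h - my;
        float* d = mcol + (size_t)nx * h;
        for (int ny = 0; ny < h; ++ny) d[ny] = kc[ny];
      }
    }
}
// scatter-add dM (N x N) into gK (2h x 2w): gK[c+n-m] += dM(n, m)
static void msg_toeplitz_adj(const fmat& dM, float* gK, int h, int w) {
  for (int mx = 0; mx < w; ++mx)
    for (int my = 0; my < h; ++my) {
      const float* mcol = dM.colptr(my + mx * h);
      for (int nx = 0; nx < w; ++nx) {
        float* kc = gK + (size_t)(w + nx - mx) * 2 * h + h - my;
        const float* sc = mcol + (size_t)nx * h;
        for (int ny = 0; ny < h; ++ny) kc[ny] += sc[ny];
      }
    }
}

// one training step; returns losses (and the lambda actually used).
// [[Rcpp::export]]
List cpp_trainer_step(SEXP ptr_, NumericVector x, NumericVector tgt,
                      NumericVector coords, NumericMatrix vis, double lr,
                      bool training = true) {
  XPtr<Trainer> ptr(ptr_);
  Trainer& T = *ptr;
  const int H = T.H, W = T.W, B = T.B, L = T.L, wdt = T.width;
  const size_t HW = (size_t)H * W;
  const float b1 = 0.9f, b2 = 0.999f, aeps = 1e-8f;

  // ---- import batch to float ----
  static thread_local fmat xin;
  xin.set_size(HW, B);
  for (size_t k = 0; k < HW * B; ++k) xin[k] = (float)x[k];

  // ---- forward U-Net ----
  std::vector<fmat> skips(T.levels);       // outputs pre-pool
  std::vector<fmat> upIn(T.levels);        // decoder upsampling inputs
  fmat colbuf, gcolbuf;
  arma::vec bsum, bsumsq;
  arma::vec* ps = training ? &bsum : nullptr;
  arma::vec* pq = training ? &bsumsq : nullptr;
  fmat h = xin;
  Shape s{H, W};
  std::vector<Shape> shp(T.levels + 1);
  for (int lv = 0; lv < T.levels; ++lv) {
    shp[lv] = s;
    ConvBlock& c1 = T.enc[2 * lv];
    ConvBlock& c2 = T.enc[2 * lv + 1];
    c1.x = std::move(h);
    fmat z1((size_t)s.H * s.W, wdt * B);
    conv_fwd(c1.x, z1, c1, s, B, colbuf, ps, pq);
    bnact_fwd(c1, z1, s, B, training, ps, pq);
    c2.x = std::move(z1);
    fmat z2((size_t)s.H * s.W, wdt * B);
    conv_fwd(c2.x, z2, c2, s, B, colbuf, ps, pq);
    bnact_fwd(c2, z2, s, B, training, ps, pq);
    skips[lv] = std::move(z2);
    fmat pooled((size_t)(s.H / 2) * (s.W / 2), wdt * B);
    avgpool_fwd(skips[lv], pooled, s, wdt, B);
    h = std::move(pooled);
    s = Shape{s.H / 2, s.W / 2};
  }
  shp[T.levels] = s;
  // decoder
  for (int lv = T.levels - 1; lv >= 0; --lv) {
    Shape so = shp[lv];
    upIn[lv] = std::move(h);
    fmat up((size_t)so.H * so.W, wdt * B);
    up2_fwd(upIn[lv], up, Shape{so.H / 2, so.W / 2}, wdt, B);
    // concat (up | skip) per image
    fmat cat((size_t)so.H * so.W, 2 * wdt * B);
    for (int b = 0; b < B; ++b) {
      cat.cols(b * 2 * wdt, b * 2 * wdt + wdt - 1) =
        up.cols(b * wdt, (b + 1) * wdt - 1);
      cat.cols(b * 2 * wdt + wdt, (b + 1) * 2 * wdt - 1) =
        skips[lv].cols(b * wdt, (b + 1) * wdt - 1);
    }
    ConvBlock& c1 = T.dec[2 * lv];
    ConvBlock& c2 = T.dec[2 * lv + 1];
    c1.x = std::move(cat);
    fmat z1((size_t)so.H * so.W, wdt * B);
    conv_fwd(c1.x, z1, c1, so, B, colbuf, ps, pq);
    bnact_fwd(c1, z1, so, B, training, ps, pq);
    c2.x = std::move(z1);
    fmat z2((size_t)so.H * so.W, wdt * B);
    conv_fwd(c2.x, z2, c2, so, B, colbuf, ps, pq);
    bnact_fwd(c2, z2, so, B, training, ps, pq);
    h = std::move(z2);
  }
  T.fin.x = std::move(h);
  fmat out(HW, L * B);
  conv_fwd(T.fin.x, out, T.fin, Shape{H, W}, B, colbuf);
  const float osc = (float)T.outScale;
  if (osc != 1.f) out *= osc;

  // ---- heatmap loss (vs double targets) ----
  double nvis = 0;
  for (int b = 0; b < B; ++b) for (int l = 0; l < L; ++l) nvis += vis(l, b);
  const double N = HW * std::max(nvis, 1.0);
  double hloss = 0;
  fmat gout(HW, L * B);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l) {
      float* po = out.colptr(b * L + l);
      float* go = gout.colptr(b * L + l);
      if (vis(l, b) == 0) { std::fill(go, go + HW, 0.f); continue; }
      const double* tp = tgt.begin() + HW * (l + (size_t)b * L);
      double acc = 0;
      for (size_t k = 0; k < HW; ++k) {
        const double df = po[k] - tp[k];
        acc += df * df;
        go[k] = (float)(2.0 * df / N);
      }
      hloss += acc;
    }
  hloss /= N;

  double closs = NA_REAL;
  // ---- refinement head ----
  fmat p, pds, sph, S, mehat, probs, gheat;
  fmat kup, spk, spb, inners;
  fmat dcoords; // expected coords (L x 2 x B flattened as (L, 2B)? keep (2, L*B))
  std::vector<float> eu(L * B), ev(L * B);
  if (T.hasGaffa) {
    const int wh = T.wh, ww = T.ww;
    const size_t N2 = (size_t)wh * ww;
    // bn on heatmaps (in place: `out` is not needed past the loss gradient)
    p = std::move(out);
    {
      ConvBlock tmp; tmp.cout = L; tmp.gamma = T.ggamma; tmp.beta = T.gbeta2;
      tmp.rm = T.grm; tmp.rv = T.grv; tmp.slope = 1.0;
      bnact_fwd(tmp, p, Shape{H, W}, B, training);
      T.grm = tmp.rm; T.grv = tmp.rv;
      T.ginvstd = std::move(tmp.invstd);
    }
    // downsample
    pds.set_size(N2, L * B);
    {
      fmat tmpr(T.tapDownR.out, W);
      for (int cb = 0; cb < L * B; ++cb)
        resize1(p.colptr(cb), pds.colptr(cb), T.tapDownR, T.tapDownC, tmpr);
    }
    sph = pds;
    const float gb = (float)T.gbeta_;
    for (size_t k = 0; k < sph.n_elem; ++k) sph[k] = softplusb(sph[k], gb);
    // kernels upsample + softplus
    kup.set_size((size_t)4 * N2, T.P);
    {
      fmat tmpr(T.tapKR.out, T.kwd);
      for (int pp = 0; pp < T.P; ++pp)
        resize1(T.kst.colptr(pp), kup.colptr(pp), T.tapKR, T.tapKC, tmpr);
    }
    spk = kup;
    for (size_t k = 0; k < spk.n_elem; ++k) spk[k] = softplusb(spk[k], gb);
    spb = T.bst;
    for (size_t k = 0; k < spb.n_elem; ++k) spb[k] = softplusb(spb[k], gb);
    // messages (Toeplitz GEMM per pair, batched over images)
    S.zeros(N2, L * B);
    inners.set_size(N2, (size_t)T.P * B);
    const float ge = (float)T.geps;
    if ((int)T.Ms.size() != T.P) T.Ms.resize(T.P);
    {
      fmat X(N2, B), Y(N2, B);
      for (int pp = 0; pp < T.P; ++pp) {
        const int i = T.pi[pp] - 1, j = T.pj[pp] - 1;
        fmat& M = T.Ms[pp];
        msg_toeplitz_f(spk.colptr(pp), wh, ww, M);
        for (int b = 0; b < B; ++b)
          std::copy(sph.colptr(b * L + j), sph.colptr(b * L + j) + N2,
                    X.colptr(b));
        Y = M * X;
        const float* bb_ = spb.colptr(pp);
        for (int b = 0; b < B; ++b) {
          float* inn = inners.colptr((size_t)pp * B + b);
          const float* Yp = Y.colptr(b);
          float* Sp = S.colptr(b * L + i);
          for (size_t k = 0; k < N2; ++k) {
            const float v = Yp[k] + bb_[k] + ge;
            inn[k] = v;
            Sp[k] += logf(v);
          }
        }
      }
    }
    // upsample S, assemble marginal energies (fused) and decode: probs holds
    // the energies after the first pass and the softmax after the second.
    probs.set_size(HW, L * B);
    {
      fmat tmpr(T.tapUpR.out, ww);
      for (int cb = 0; cb < L * B; ++cb) {
        float* pr = probs.colptr(cb);
        resize1(S.colptr(cb), pr, T.tapUpR, T.tapUpC, tmpr);
        const float* pc = p.colptr(cb);
        float mx = -1e30f;
        for (size_t k = 0; k < HW; ++k) {
          pr[k] += logf(softplusb(pc[k] + ge, gb));
          if (pr[k] > mx) mx = pr[k];
        }
        double sum = 0, du = 0, dv = 0;
        for (int cx = 0; cx < W; ++cx) {
          float* col = pr + (size_t)cx * H;
          double cs = 0, vs = 0;
          for (int cy = 0; cy < H; ++cy) {
            const float e = expf(col[cy] - mx);
            col[cy] = e;
            cs += e; vs += (double)e * cy;
          }
          sum += cs; du += cs * cx; dv += vs;
        }
        const float inv = (float)(1.0 / sum);
        for (size_t k = 0; k < HW; ++k) pr[k] *= inv;
        eu[cb] = (float)(du / sum); ev[cb] = (float)(dv / sum);
      }
    }
    // coordinate loss (mean over components of visible landmarks)
    double cl = 0;
    const double NC = 2.0 * std::max(nvis, 1.0);
    fmat gco(2, L * B, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int l = 0; l < L; ++l) {
        if (vis(l, b) == 0) continue;
        const double tu = coords[l + (size_t)b * 2 * L];
        const double tv = coords[l + L + (size_t)b * 2 * L];
        const double duu = eu[b * L + l] - tu, dvv = ev[b * L + l] - tv;
        cl += duu * duu + dvv * dvv;
        gco(0, b * L + l) = (float)(2.0 * duu / NC);
        gco(1, b * L + l) = (float)(2.0 * dvv / NC);
      }
    cl /= NC;
    closs = cl;
    if (!R_finite(T.lambda)) T.lambda = hloss / std::max(cl, 1e-12);
    const float lam = (float)T.lambda;

    // ---- backward through refinement ----
    // per channel: dsnt backward (in place on probs), unary branch into gp,
    // upsample-adjoint into gS
    fmat gS(N2, L * B, arma::fill::zeros);
    fmat gp(HW, L * B);
    const float geps_ = (float)T.geps;
    {
      fmat tmpr(T.tapUpR.out, ww);
      for (int cb = 0; cb < L * B; ++cb) {
        float* pr = probs.colptr(cb);
        const float* pc = p.colptr(cb);
        float* gpc = gp.colptr(cb);
        const float gu = lam * gco(0, cb), gv = lam * gco(1, cb);
        const float ceu = eu[cb], cev = ev[cb];
        for (int cx = 0; cx < W; ++cx) {
          float* col = pr + (size_t)cx * H;
          float* gpcol = gpc + (size_t)cx * H;
          const float* pcol = pc + (size_t)cx * H;
          const float du = (cx - ceu) * gu;
          for (int cy = 0; cy < H; ++cy) {
            const float gm = col[cy] * (du + (cy - cev) * gv);
            col[cy] = gm;  // probs now holds gme
            const float xx = pcol[cy] + geps_;
            gpcol[cy] = gm * sigmoidb(xx, gb) / softplusb(xx, gb);
          }
        }
        resize1_adj(pr, gS.colptr(cb), T.tapUpR, T.tapUpC, tmpr);
      }
    }
    // message backward
    fmat gsph(N2, L * B, arma::fill::zeros);
    fmat gkup((size_t)4 * N2, T.P, arma::fill::zeros);
    fmat gbst(N2, T.P, arma::fill::zeros);
    {
      fmat X(N2, B), G(N2, B), GH(N2, B), dM;
      for (int pp = 0; pp < T.P; ++pp) {
        const int i = T.pi[pp] - 1, j = T.pj[pp] - 1;
        const fmat& M = T.Ms[pp];
        float* gbp = gbst.colptr(pp);
        for (int b = 0; b < B; ++b) {
          const float* inn = inners.colptr((size_t)pp * B + b);
          const float* gSp = gS.colptr(b * L + i);
          float* Gp = G.colptr(b);
          for (size_t k = 0; k < N2; ++k) {
            const float gi = gSp[k] / inn[k];
            Gp[k] = gi;
            gbp[k] += gi;
          }
          std::copy(sph.colptr(b * L + j), sph.colptr(b * L + j) + N2,
                    X.colptr(b));
        }
        GH = M.t() * G;
        for (int b = 0; b < B; ++b) {
          float* dst = gsph.colptr(b * L + j);
          const float* src = GH.colptr(b);
          for (size_t k = 0; k < N2; ++k) dst[k] += src[k];
        }
        dM = G * X.t();
        msg_toeplitz_adj(dM, gkup.colptr(pp), wh, ww);
      }
    }
    // chain rules: kernels (softplus then resize-adjoint), biases, heatmaps
    for (size_t k = 0; k < gkup.n_elem; ++k) gkup[k] *= sigmoidb(kup[k], gb);
    fmat gkst((size_t)T.kh * T.kwd, T.P, arma::fill::zeros);
    {
      fmat tmpr(T.tapKR.out, T.kwd);
      for (int pp = 0; pp < T.P; ++pp)
        resize1_adj(gkup.colptr(pp), gkst.colptr(pp), T.tapKR, T.tapKC, tmpr);
    }
    for (size_t k = 0; k < gbst.n_elem; ++k) gbst[k] *= sigmoidb(T.bst[k], gb);
    for (size_t k = 0; k < gsph.n_elem; ++k) gsph[k] *= sigmoidb(pds[k], gb);
    // upsample-adjoint of gsph into gp
    {
      fmat tmpr(T.tapDownR.out, W);
      for (int cb = 0; cb < L * B; ++cb)
        resize1_adj(gsph.colptr(cb), gp.colptr(cb), T.tapDownR, T.tapDownC, tmpr);
    }
    // bn backward on heatmaps
    fvec ggg, ggb;
    {
      ConvBlock tmp; tmp.cout = L; tmp.gamma = T.ggamma; tmp.beta = T.gbeta2;
      tmp.invstd = T.ginvstd; tmp.slope = 1.0;
      bnact_bwd(tmp, gp, p, Shape{H, W}, B, training, ggg, ggb);
    }
    gout += gp;
    // adam updates for gaffa parameters
    T.t += 1;
    const float bc1 = 1 - std::pow(b1, T.t), bc2 = 1 - std::pow(b2, T.t);
    adam_update(T.kst, gkst, T.akst.mw, T.akst.vw, (float)lr, b1, b2, aeps, bc1, bc2);
    adam_update(T.bst, gbst, T.abst.mw, T.abst.vw, (float)lr, b1, b2, aeps, bc1, bc2);
    adam_update(T.ggamma, ggg, T.mgg, T.vgg, (float)lr, b1, b2, aeps, bc1, bc2);
    adam_update(T.gbeta2, ggb, T.mgb, T.vgb, (float)lr, b1, b2, aeps, bc1, bc2);
  } else {
    T.t += 1;
  }
  const float bc1 = 1 - std::pow(b1, T.t), bc2 = 1 - std::pow(b2, T.t);

  // ---- backward U-Net ----
  if (osc != 1.f) gout *= osc;
  fmat gw; fvec gbv, ggamma, gbeta;
  fmat g = std::move(gout);
  {
    fmat gx(HW, wdt * B);
    conv_bwd(T.fin.x, g, T.fin, Shape{H, W}, B, gw, gbv, &gx, colbuf, gcolbuf);
    adam_update(T.fin.w, gw, T.fin.aw.mw, T.fin.aw.vw, (float)lr, b1, b2, aeps, bc1, bc2);
    adam_update(T.fin.b, gbv, T.fin.aw.mb, T.fin.aw.vb, (float)lr, b1, b2, aeps, bc1, bc2);
    g = std::move(gx);
  }
  std::vector<fmat> gskips(T.levels);
  for (int lv = 0; lv < T.levels; ++lv) {
    Shape so = shp[lv];
    ConvBlock& c2 = T.dec[2 * lv + 1];
    ConvBlock& c1 = T.dec[2 * lv];
    bnact_bwd(c2, g, lv == 0 ? T.fin.x : upIn[lv - 1], so, B, training,
              ggamma, gbeta);
    {
      fmat gx((size_t)so.H * so.W, wdt * B);
      conv_bwd(c2.x, g, c2, so, B, gw, gbv, &gx, colbuf, gcolbuf);
      adam_update(c2.w, gw, c2.aw.mw, c2.aw.vw, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c2.b, gbv, c2.aw.mb, c2.aw.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c2.gamma, ggamma, c2.ag.mb, c2.ag.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c2.beta, gbeta, c2.agb.mb, c2.agb.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      g = std::move(gx);
    }
    bnact_bwd(c1, g, c2.x, so, B, training, ggamma, gbeta);
    {
      fmat gx((size_t)so.H * so.W, 2 * wdt * B);
      conv_bwd(c1.x, g, c1, so, B, gw, gbv, &gx, colbuf, gcolbuf);
      adam_update(c1.w, gw, c1.aw.mw, c1.aw.vw, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c1.b, gbv, c1.aw.mb, c1.aw.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c1.gamma, ggamma, c1.ag.mb, c1.ag.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c1.beta, gbeta, c1.agb.mb, c1.agb.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      // split concat gradient
      fmat gup((size_t)so.H * so.W, wdt * B);
      gskips[lv].set_size((size_t)so.H * so.W, wdt * B);
      for (int b = 0; b < B; ++b) {
        gup.cols(b * wdt, (b + 1) * wdt - 1) =
          gx.cols(b * 2 * wdt, b * 2 * wdt + wdt - 1);
        gskips[lv].cols(b * wdt, (b + 1) * wdt - 1) =
          gx.cols(b * 2 * wdt + wdt, (b + 1) * 2 * wdt - 1);
      }
      fmat gprev((size_t)(so.H / 2) * (so.W / 2), wdt * B);
      up2_bwd(gup, gprev, Shape{so.H / 2, so.W / 2}, wdt, B);
      g = std::move(gprev);
    }
  }
  for (int lv = T.levels - 1; lv >= 0; --lv) {
    Shape so = shp[lv];
    fmat gpool((size_t)so.H * so.W, wdt * B, arma::fill::zeros);
    avgpool_bwd(g, gpool, so, wdt, B);
    gpool += gskips[lv];
    g = std::move(gpool);
    ConvBlock& c2 = T.enc[2 * lv + 1];
    ConvBlock& c1 = T.enc[2 * lv];
    bnact_bwd(c2, g, skips[lv], so, B, training, ggamma, gbeta);
    {
      fmat gx((size_t)so.H * so.W, wdt * B);
      conv_bwd(c2.x, g, c2, so, B, gw, gbv, &gx, colbuf, gcolbuf);
      adam_update(c2.w, gw, c2.aw.mw, c2.aw.vw, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c2.b, gbv, c2.aw.mb, c2.aw.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c2.gamma, ggamma, c2.ag.mb, c2.ag.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c2.beta, gbeta, c2.agb.mb, c2.agb.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      g = std::move(gx);
    }
    bnact_bwd(c1, g, c2.x, so, B, training, ggamma, gbeta);
    {
      const bool needGx = lv > 0;
      fmat gx;
      if (needGx) gx.set_size((size_t)so.H * so.W, c1.cin * B);
      conv_bwd(c1.x, g, c1, so, B, gw, gbv, needGx ? &gx : nullptr, colbuf, gcolbuf);
      adam_update(c1.w, gw, c1.aw.mw, c1.aw.vw, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c1.b, gbv, c1.aw.mb, c1.aw.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c1.gamma, ggamma, c1.ag.mb, c1.ag.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      adam_update(c1.beta, gbeta, c1.agb.mb, c1.agb.vb, (float)lr, b1, b2, aeps, bc1, bc2);
      if (needGx) g = std::move(gx);
    }
  }
  return List::create(_["heatmapLoss"] = hloss, _["coordLoss"] = closs,
                      _["lambda"] = T.lambda);
}

// export trained weights back into the R model structures (double precision)
// [[Rcpp::export]]
List cpp_trainer_export(SEXP ptr_) {
  XPtr<Trainer> ptr(ptr_);
  Trainer& T = *ptr;
  List params, buffers;
  auto expBlock = [&](const ConvBlock& c, std::string nm) {
    NumericMatrix w(c.w.n_rows, c.w.n_cols);
    for (size_t k = 0; k < c.w.n_elem; ++k) w[k] = c.w[k];
    List pb = List::create(_["w"] = w, _["b"] = NumericVector(c.b.begin(), c.b.end()),
                           _["gamma"] = NumericVector(c.gamma.begin(), c.gamma.end()),
                           _["beta"] = NumericVector(c.beta.begin(), c.beta.end()));
    params[nm] = pb;
    buffers[nm] = List::create(_["rm"] = NumericVector(c.rm.begin(), c.rm.end()),
                               _["rv"] = NumericVector(c.rv.begin(), c.rv.end()));
  };
  for (int lv = 1; lv <= T.levels; ++lv) {
    expBlock(T.enc[2 * (lv - 1)], "enc" + std::to_string(lv) + "_c1");
    expBlock(T.enc[2 * (lv - 1) + 1], "enc" + std::to_string(lv) + "_c2");
  }
  for (int lv = 1; lv <= T.levels; ++lv) {
    expBlock(T.dec[2 * (lv - 1)], "dec" + std::to_string(lv) + "_c1");
    expBlock(T.dec[2 * (lv - 1) + 1], "dec" + std::to_string(lv) + "_c2");
  }
  {
    NumericMatrix w(T.fin.w.n_rows, T.fin.w.n_cols);
    for (size_t k = 0; k < T.fin.w.n_elem; ++k) w[k] = T.fin.w[k];
    params["final"] = List::create(_["w"] = w,
      _["b"] = NumericVector(T.fin.b.begin(), T.fin.b.end()));
  }
  List out = List::create(_["params"] = params, _["buffers"] = buffers,
                          _["lambda"] = T.lambda);
  if (T.hasGaffa) {
    List kern(T.P), bias(T.P);
    for (int p = 0; p < T.P; ++p) {
      NumericMatrix km(T.kh, T.kwd);
      for (size_t k = 0; k < (size_t)T.kh * T.kwd; ++k) km[k] = T.kst(k, p);
      kern[p] = km;
      NumericMatrix bm(T.wh, T.ww);
      for (size_t k = 0; k < (size_t)T.wh * T.ww; ++k) bm[k] = T.bst(k, p);
      bias[p] = bm;
    }
    out["gaffaParams"] = List::create(
      _["kernels"] = kern, _["biases"] = bias,
      _["bnGamma"] = NumericVector(T.ggamma.begin(), T.ggamma.end()),
      _["bnBeta"] = NumericVector(T.gbeta2.begin(), T.gbeta2.end()));
    out["gaffaBuffers"] = List::create(
      _["rm"] = NumericVector(T.grm.begin(), T.grm.end()),
      _["rv"] = NumericVector(T.grv.begin(), T.grv.end()));
  }
  return out;
}
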