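// Low-level numerical kernels for the localization engine.
// Layout convention everywhere: images/feature maps are column-major R arrays
// [H, W, C, B] (row index = y, col index = x), weights for a kxk convolution
// are (k*k*cin) x cout matrices with row index ki + kj*kh + ch*kh*kw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector make4(int a, int b, int c, int d) {
  NumericVector v(R_xlen_t((size_t)a * b * c * d));
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// uninitialized variant for outputs that are fully overwritten
static NumericVector make4_raw(int a, int b, int c, int d) {
  NumericVector v(no_init(R_xlen_t((size_t)a * b * c * d)));
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::cube as_cube_view(const NumericVector& x, int H, int W, int CB) {
  return arma::cube(const_cast<double*>(x.begin()), H, W, CB, false, true);
}

// Column-tiled im2col convolution: process output columns in stripes whose
// im2col block stays cache-resident, so feature maps are read and written
// roughly once per layer (this host is memory-bandwidth bound).
static void im2col_block(const double* x, int H, int W, int C, int kh, int kw,
                         int ox0, int nox, arma::mat& col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* dst = col.colptr(ki + kj * kh + c * kh * kw);
        for (int oi = 0; oi < nox; ++oi) {
          const int ix = ox0 + oi + kj - pw;
          double* d = dst + (size_t)oi * H;
          if (ix < 0 || ix >= W) { std::fill(d, d + H, 0.0); continue; }
          const double* src = xc + (size_t)ix * H;
          const int lo = std::max(0, ph - ki);
          const int hi = std::min(H, H + ph - ki);
          if (lo > 0) std::fill(d, d + lo, 0.0);
          if (hi < H) std::fill(d + hi, d + H, 0.0);
          if (hi > lo) std::copy(src + lo + ki - ph, src + hi + ki - ph, d + lo);
        }
      }
    }
  }
}

static int conv_block_cols(int H, int K) {
  // keep the im2col block around 512 KB
  int nb = (int)(65536 / std::max(1, H * K / 8));
  return std::max(4, std::min(64, nb));
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                             int kh, int kw) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int K = kh * kw * C, Cout = w.ncol();
  if (w.nrow() != K) stop("conv weight shape mismatch");
  NumericVector y = make4_raw(H, W, Cout, B);
  arma::mat wm(w.begin(), K, Cout, false, true);
  const int NB = conv_block_cols(H, K);
  arma::mat col((size_t)H * NB, K);
  for (int bimg = 0; bimg < B; ++bimg) {
    const double* xb = x.begin() + (size_t)bimg * H * W * C;
    arma::mat ym(y.begin() + (size_t)bimg * H * W * Cout, (size_t)H * W, Cout,
                 false, true);
    for (int ox0 = 0; ox0 < W; ox0 += NB) {
      const int nox = std::min(NB, W - ox0);
      im2col_block(xb, H, W, C, kh, kw, ox0, nox, col);
      ym.rows((size_t)ox0 * H, (size_t)(ox0 + nox) * H - 1) =
        col.head_rows((size_t)nox * H) * wm;
    }
    for (int c = 0; c < Cout; ++c) ym.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector gy,
                    int kh, int kw, bool need_gx = true) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int K = kh * kw * C, Cout = w.ncol();
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat wm(w.begin(), K, Cout, false, true);
  NumericVector gx = need_gx ? make4(H, W, C, B) : make4(1, 1, 1, 1);
  arma::mat gw(K, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  const int NB = conv_block_cols(H, K);
  arma::mat col((size_t)H * NB, K);
  arma::mat gcol((size_t)H * NB, K);
  for (int bimg = 0; bimg < B; ++bimg) {
    const double* xb = x.begin() + (size_t)bimg * H * W * C;
    arma::mat gym(const_cast<double*>(gy.begin()) + (size_t)bimg * H * W * Cout,
                  (size_t)H * W, Cout, false, true);
    for (int ox0 = 0; ox0 < W; ox0 += NB) {
      const int nox = std::min(NB, W - ox0);
      im2col_block(xb, H, W, C, kh, kw, ox0, nox, col);
      arma::mat gyb = gym.rows((size_t)ox0 * H, (size_t)(ox0 + nox) * H - 1);
      gw += col.head_rows((size_t)nox * H).t() * gyb;
      gb += arma::sum(gyb, 0).t();
      if (!need_gx) continue;
      gcol.head_rows((size_t)nox * H) = gyb * wm.t();
      // scatter-add this column stripe back into gx
      double* gxb = gx.begin() + (size_t)bimg * H * W * C;
      for (int c = 0; c < C; ++c) {
        double* xc = gxb + (size_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki) {
            const double* src = gcol.colptr(ki + kj * kh + c * kh * kw);
            for (int oi = 0; oi < nox; ++oi) {
              const int ix = ox0 + oi + kj - pw;
              if (ix < 0 || ix >= W) continue;
              double* dstcol = xc + (size_t)ix * H;
              const double* scol = src + (size_t)oi * H;
              const int lo = std::max(0, ph - ki);
              const int hi = std::min(H, H + ph - ki);
              for (int oy = lo; oy < hi; ++oy) dstcol[oy + ki - ph] += scol[oy];
            }
          }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = wrap(gw), _["gb"] = wrap(gb));
}

// Convolution over the logical channel concatenation [xa ; xb] without
// materializing the concatenated array (decoder skip connections).
// [[Rcpp::export]]
NumericVector cpp_conv2d_cat_fwd(NumericVector xa, NumericVector xb,
                                 NumericMatrix w, NumericVector b,
                                 int kh, int kw) {
  IntegerVector da = xa.attr("dim"), db = xb.attr("dim");
  const int H = da[0], W = da[1], Ca = da[2], Cb = db[2], B = da[3];
  const int K = kh * kw * (Ca + Cb), Cout = w.ncol();
  if (w.nrow() != K) stop("conv weight shape mismatch");
  NumericVector y = make4_raw(H, W, Cout, B);
  arma::mat wm(w.begin(), K, Cout, false, true);
  const int NB = conv_block_cols(H, K);
  arma::mat col((size_t)H * NB, K);
  const int Ka = kh * kw * Ca;
  for (int bimg = 0; bimg < B; ++bimg) {
    const double* pa = xa.begin() + (size_t)bimg * H * W * Ca;
    const double* pb = xb.begin() + (size_t)bimg * H * W * Cb;
    arma::mat ym(y.begin() + (size_t)bimg * H * W * Cout, (size_t)H * W, Cout,
                 false, true);
    for (int ox0 = 0; ox0 < W; ox0 += NB) {
      const int nox = std::min(NB, W - ox0);
      im2col_block(pa, H, W, Ca, kh, kw, ox0, nox, col);
      arma::mat colb(col.colptr(Ka), (size_t)H * NB, kh * kw * Cb, false, true);
      im2col_block(pb, H, W, Cb, kh, kw, ox0, nox, colb);
      ym.rows((size_t)ox0 * H, (size_t)(ox0 + nox) * H - 1) =
        col.head_rows((size_t)nox * H) * wm;
    }
    for (int c = 0; c < Cout; ++c) ym.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_cat_bwd(NumericVector xa, NumericVector xb, NumericMatrix w,
                        NumericVector gy, int kh, int kw) {
  IntegerVector da = xa.attr("dim"), db = xb.attr("dim");
  const int H = da[0], W = da[1], Ca = da[2], Cb = db[2], B = da[3];
  const int K = kh * kw * (Ca + Cb), Cout = w.ncol();
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat wm(w.begin(), K, Cout, false, true);
  NumericVector gxa = make4(H, W, Ca, B), gxb = make4(H, W, Cb, B);
  arma::mat gw(K, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  const int NB = conv_block_cols(H, K);
  arma::mat col((size_t)H * NB, K);
  arma::mat gcol((size_t)H * NB, K);
  const int Ka = kh * kw * Ca;
  for (int bimg = 0; bimg < B; ++bimg) {
    const double* pa = xa.begin() + (size_t)bimg * H * W * Ca;
    const double* pb = xb.begin() + (size_t)bimg * H * W * Cb;
    arma::mat gym(const_cast<double*>(gy.begin()) + (size_t)bimg * H * W * Cout,
                  (size_t)H * W, Cout, false, true);
    for (int ox0 = 0; ox0 < W; ox0 += NB) {
      const int nox = std::min(NB, W - ox0);
      im2col_block(pa, H, W, Ca, kh, kw, ox0, nox, col);
      arma::mat colb(col.colptr(Ka), (size_t)H * NB, kh * kw * Cb, false, true);
      im2col_block(pb, H, W, Cb, kh, kw, ox0, nox, colb);
      arma::mat gyb = gym.rows((size_t)ox0 * H, (size_t)(ox0 + nox) * H - 1);
      gw += col.head_rows((size_t)nox * H).t() * gyb;
      gb += arma::sum(gyb, 0).t();
      gcol.head_rows((size_t)nox * H) = gyb * wm.t();
      for (int part = 0; part < 2; ++part) {
        const int C = part == 0 ? Ca : Cb;
        const int koff = part == 0 ? 0 : Ka;
        double* gxp = (part == 0 ? gxa.begin() : gxb.begin()) +
          (size_t)bimg * H * W * C;
        for (int c = 0; c < C; ++c) {
          double* xc = gxp + (size_t)c * H * W;
          for (int kj = 0; kj < kw; ++kj)
            for (int ki = 0; ki < kh; ++ki) {
              const double* src = gcol.colptr(koff + ki + kj * kh + c * kh * kw);
              for (int oi = 0; oi < nox; ++oi) {
                const int ix = ox0 + oi + kj - pw;
                if (ix < 0 || ix >= W) continue;
                double* dstcol = xc + (size_t)ix * H;
                const double* scol = src + (size_t)oi * H;
                const int lo = std::max(0, ph - ki);
                const int hi = std::min(H, H + ph - ki);
                for (int oy = lo; oy < hi; ++oy) dstcol[oy + ki - ph] += scol[oy];
              }
            }
        }
      }
    }
  }
  return List::create(_["gxa"] = gxa, _["gxb"] = gxb,
                      _["gw"] = wrap(gw), _["gb"] = wrap(gb));
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], CB = d[2] * d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4_raw(Ho, Wo, d[2], d[3]);
  for (int s = 0; s < CB; ++s) {
    const double* xs = x.begin() + (size_t)s * H * W;
    double* ys = y.begin() + (size_t)s * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy) {
        const double* p = xs + (size_t)(2 * ox) * H + 2 * oy;
        ys[oy + (size_t)ox * Ho] = 0.25 * (p[0] + p[1] + p[H] + p[H + 1]);
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector g, int H, int W) {
  IntegerVector d = g.attr("dim");
  const int Ho = d[0], Wo = d[1], CB = d[2] * d[3];
  NumericVector gx = make4(H, W, d[2], d[3]);
  for (int s = 0; s < CB; ++s) {
    const double* gs = g.begin() + (size_t)s * Ho * Wo;
    double* xs = gx.begin() + (size_t)s * H * W;
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy) {
        const double v = 0.25 * gs[oy + (size_t)ox * Ho];
        double* p = xs + (size_t)(2 * ox) * H + 2 * oy;
        p[0] += v; p[1] += v; p[H] += v; p[H + 1] += v;
      }
  }
  return gx;
}

// Fixed x2 bilinear upsampling (align_corners = FALSE convention: output pixel
// o samples input coordinate (o + 0.5)/2 - 0.5, edge-clamped).
static void up2_taps(int Ho, int Hi, arma::ivec& i0, arma::ivec& i1, arma::vec& w1) {
  i0.set_size(Ho); i1.set_size(Ho); w1.set_size(Ho);
  for (int o = 0; o < Ho; ++o) {
    double pos = (o + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(pos);
    double fr = pos - lo;
    int l0 = std::min(std::max(lo, 0), Hi - 1);
    int l1 = std::min(std::max(lo + 1, 0), Hi - 1);
    i0[o] = l0; i1[o] = l1; w1[o] = fr;
  }
}

// [[Rcpp::export]]
NumericVector cpp_up2_bilinear_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], CB = d[2] * d[3];
  const int Ho = 2 * H, Wo = 2 * W;
  arma::ivec ri0, ri1, ci0, ci1; arma::vec rw1, cw1;
  up2_taps(Ho, H, ri0, ri1, rw1);
  up2_taps(Wo, W, ci0, ci1, cw1);
  NumericVector y = make4_raw(Ho, Wo, d[2], d[3]);
  for (int s = 0; s < CB; ++s) {
    const double* xs = x.begin() + (size_t)s * H * W;
    double* ys = y.begin() + (size_t)s * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox) {
      const double* c0 = xs + (size_t)ci0[ox] * H;
      const double* c1 = xs + (size_t)ci1[ox] * H;
      const double wc = cw1[ox];
      for (int oy = 0; oy < Ho; ++oy) {
        const double wr = rw1[oy];
        const int r0 = ri0[oy], r1 = ri1[oy];
        ys[oy + (size_t)ox * Ho] =
          (1 - wr) * ((1 - wc) * c0[r0] + wc * c1[r0]) +
          wr * ((1 - wc) * c0[r1] + wc * c1[r1]);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_up2_bilinear_bwd(NumericVector g) {
  IntegerVector d = g.attr("dim");
  const int Ho = d[0], Wo = d[1], CB = d[2] * d[3];
  const int H = Ho / 2, W = Wo / 2;
  arma::ivec ri0, ri1, ci0, ci1; arma::vec rw1, cw1;
  up2_taps(Ho, H, ri0, ri1, rw1);
  up2_taps(Wo, W, ci0, ci1, cw1);
  NumericVector gx = make4(H, W, d[2], d[3]);
  for (int s = 0; s < CB; ++s) {
    const double* gs = g.begin() + (size_t)s * Ho * Wo;
    double* xs = gx.begin() + (size_t)s * H * W;
    for (int ox = 0; ox < Wo; ++ox) {
      double* c0 = xs + (size_t)ci0[ox] * H;
      double* c1 = xs + (size_t)ci1[ox] * H;
      const double wc = cw1[ox];
      for (int oy = 0; oy < Ho; ++oy) {
        const double v = gs[oy + (size_t)ox * Ho];
        const double wr = rw1[oy];
        const int r0 = ri0[oy], r1 = ri1[oy];
        c0[r0] += (1 - wr) * (1 - wc) * v;
        c1[r0] += (1 - wr) * wc * v;
        c0[r1] += wr * (1 - wc) * v;
        c1[r1] += wr * wc * v;
      }
    }
  }
  return gx;
}

// Separable 4-tap resampling (bicubic); taps precomputed on the R side.
// ridx/cidx are 0-based out_dim x 4 integer matrices, rw/cw matching weights.
// [[Rcpp::export]]
NumericVector cpp_resize4_fwd(NumericVector x, IntegerMatrix ridx, NumericMatrix rw,
                              IntegerMatrix cidx, NumericMatrix cw) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], CB = d[2] * d[3];
  const int Ho = ridx.nrow(), Wo = cidx.nrow();
  NumericVector y = make4_raw(Ho, Wo, d[2], d[3]);
  arma::mat tmp(Ho, W);
  // contiguous tap tables
  std::vector<int> ri(Ho * 4), ci(Wo * 4);
  std::vector<double> rv(Ho * 4), cv(Wo * 4);
  for (int o = 0; o < Ho; ++o) for (int t = 0; t < 4; ++t) {
    ri[4 * o + t] = ridx(o, t); rv[4 * o + t] = rw(o, t);
  }
  for (int o = 0; o < Wo; ++o) for (int t = 0; t < 4; ++t) {
    ci[4 * o + t] = cidx(o, t); cv[4 * o + t] = cw(o, t);
  }
  for (int s = 0; s < CB; ++s) {
    const double* xs = x.begin() + (size_t)s * H * W;
    for (int c = 0; c < W; ++c) {
      const double* col = xs + (size_t)c * H;
      double* tc = tmp.colptr(c);
      for (int o = 0; o < Ho; ++o) {
        const int* idx = &ri[4 * o]; const double* wv = &rv[4 * o];
        tc[o] = wv[0] * col[idx[0]] + wv[1] * col[idx[1]] +
                wv[2] * col[idx[2]] + wv[3] * col[idx[3]];
      }
    }
    double* ys = y.begin() + (size_t)s * Ho * Wo;
    for (int oc = 0; oc < Wo; ++oc) {
      double* out = ys + (size_t)oc * Ho;
      const int* idx = &ci[4 * oc]; const double* wv = &cv[4 * oc];
      const double* c0 = tmp.colptr(idx[0]); const double* c1 = tmp.colptr(idx[1]);
      const double* c2 = tmp.colptr(idx[2]); const double* c3 = tmp.colptr(idx[3]);
      for (int o = 0; o < Ho; ++o)
        out[o] = wv[0] * c0[o] + wv[1] * c1[o] + wv[2] * c2[o] + wv[3] * c3[o];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize4_bwd(NumericVector g, IntegerMatrix ridx, NumericMatrix rw,
                              IntegerMatrix cidx, NumericMatrix cw,
                              int in_h, int in_w) {
  IntegerVector d = g.attr("dim");
  const int Ho = d[0], Wo = d[1], CB = d[2] * d[3];
  NumericVector gx = make4(in_h, in_w, d[2], d[3]);
  arma::mat tmp(Ho, in_w);
  for (int s = 0; s < CB; ++s) {
    const double* gs = g.begin() + (size_t)s * Ho * Wo;
    tmp.zeros();
    // transpose of column pass
    for (int oc = 0; oc < Wo; ++oc) {
      const double* gcol = gs + (size_t)oc * Ho;
      for (int t = 0; t < 4; ++t) {
        double* dst = tmp.colptr(cidx(oc, t));
        const double wgt = cw(oc, t);
        for (int o = 0; o < Ho; ++o) dst[o] += wgt * gcol[o];
      }
    }
    // transpose of row pass
    double* xs = gx.begin() + (size_t)s * in_h * in_w;
    for (int c = 0; c < in_w; ++c) {
      double* dstcol = xs + (size_t)c * in_h;
      const double* src = tmp.colptr(c);
      for (int o = 0; o < Ho; ++o) {
        const double v = src[o];
        for (int t = 0; t < 4; ++t) dstcol[ridx(o, t)] += rw(o, t) * v;
      }
    }
  }
  return gx;
}

// ---- Message convolution for the sum-product refinement ----
// True convolution of a (2h x 2w) kernel K with an (h x w) map, output cropped
// to the centred h x w window: out[y,x] = sum_{p,q} map[p,q] * K[h+y-p, w+x-q]
// (0-based). Realized as a dense Toeplitz matrix times the vectorized maps so
// BLAS carries the batch.

static arma::mat msg_toeplitz(const arma::mat& K, int h, int w) {
  const int N = h * w;
  arma::mat M(N, N);
  for (int px = 0; px < w; ++px)
    for (int py = 0; py < h; ++py) {
      const int p = py + px * h;
      for (int nx = 0; nx < w; ++nx) {
        const double* kcol = K.colptr(w + nx - px);
        double* mcol = M.colptr(p) + (size_t)nx * h;
        for (int ny = 0; ny < h; ++ny) mcol[ny] = kcol[h + ny - py];
      }
    }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_msgconv_fwd(NumericVector hmap, NumericMatrix K) {
  IntegerVector d = hmap.attr("dim");
  const int h = d[0], w = d[1], B = d[2];
  arma::mat Km(K.begin(), 2 * h, 2 * w, false, true);
  arma::mat M = msg_toeplitz(Km, h, w);
  arma::mat X(const_cast<double*>(hmap.begin()), h * w, B, false, true);
  NumericVector y(Dimension(h, w, B));
  arma::mat Y(y.begin(), h * w, B, false, true);
  Y = M * X;
  return y;
}

// [[Rcpp::export]]
List cpp_msgconv_bwd(NumericVector hmap, NumericMatrix K, NumericVector g) {
  IntegerVector d = hmap.attr("dim");
  const int h = d[0], w = d[1], B = d[2];
  arma::mat Km(K.begin(), 2 * h, 2 * w, false, true);
  arma::mat M = msg_toeplitz(Km, h, w);
  arma::mat X(const_cast<double*>(hmap.begin()), h * w, B, false, true);
  arma::mat G(const_cast<double*>(g.begin()), h * w, B, false, true);
  NumericVector gh(Dimension(h, w, B));
  arma::mat GH(gh.begin(), h * w, B, false, true);
  GH = M.t() * G;
  arma::mat dM = G * X.t(); // N x N
  NumericMatrix gK(2 * h, 2 * w);
  arma::mat gKm(gK.begin(), 2 * h, 2 * w, false, true);
  for (int px = 0; px < w; ++px)
    for (int py = 0; py < h; ++py) {
      const int p = py + px * h;
      for (int nx = 0; nx < w; ++nx) {
        double* kcol = gKm.colptr(w + nx - px);
        const double* mcol = dM.colptr(p) + (size_t)nx * h;
        for (int ny = 0; ny < h; ++ny) kcol[h + ny - py] += mcol[ny];
      }
    }
  return List::create(_["gh"] = gh, _["gk"] = gK);
}

// ---- fused batch normalization + leaky activation ----
// Per-channel statistics over (H, W, B). Returns the post-activation map,
// xhat and invstd for backprop, and updated running statistics. slope = 1
// gives a linear (no-op) activation.

// [[Rcpp::export]]
List cpp_bnact_fwd(NumericVector z, NumericVector gamma, NumericVector beta,
                   NumericVector rm, NumericVector rv, bool training,
                   double slope, double momentum, double eps) {
  IntegerVector d = z.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        const double* p = z.begin() + HW * (c + (size_t)b * C);
        for (size_t k = 0; k < HW; ++k) { s += p[k]; s2 += p[k] * p[k]; }
      }
      const double n = (double)HW * B;
      mu[c] = s / n;
      var[c] = std::max(s2 / n - mu[c] * mu[c], 0.0);
    }
  } else {
    mu = clone(rm); var = clone(rv); eps = 1e-8;
  }
  NumericVector nrm(C), nrv(C);
  for (int c = 0; c < C; ++c) {
    nrm[c] = training ? (1 - momentum) * rm[c] + momentum * mu[c] : rm[c];
    nrv[c] = training ? (1 - momentum) * rv[c] + momentum * var[c] : rv[c];
  }
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  NumericVector y = make4_raw(H, W, C, B);
  NumericVector xhat = make4_raw(H, W, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* p = z.begin() + HW * (c + (size_t)b * C);
      double* xh = xhat.begin() + HW * (c + (size_t)b * C);
      double* yy = y.begin() + HW * (c + (size_t)b * C);
      const double m = mu[c], is = invstd[c], ga = gamma[c], be = beta[c];
      for (size_t k = 0; k < HW; ++k) {
        const double x = (p[k] - m) * is;
        xh[k] = x;
        double v = ga * x + be;
        yy[k] = v < 0 ? slope * v : v;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rm"] = nrm, _["rv"] = nrv);
}

// [[Rcpp::export]]
List cpp_bnact_bwd(NumericVector g, NumericVector xhat, NumericVector invstd,
                   NumericVector gamma, NumericVector beta, double slope,
                   bool training) {
  IntegerVector d = g.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector gz = make4_raw(H, W, C, B);
  NumericVector ggamma(C), gbeta(C);
  const double n = (double)HW * B;
  for (int c = 0; c < C; ++c) {
    const double ga = gamma[c], be = beta[c], is = invstd[c];
    double s1 = 0, s2 = 0, sgg = 0, sgb = 0;
    // first pass: activation backward + reductions
    for (int b = 0; b < B; ++b) {
      const double* gg = g.begin() + HW * (c + (size_t)b * C);
      const double* xh = xhat.begin() + HW * (c + (size_t)b * C);
      for (size_t k = 0; k < HW; ++k) {
        const double ybn = ga * xh[k] + be;
        const double gact = ybn < 0 ? gg[k] * slope : gg[k];
        sgg += gact * xh[k];
        sgb += gact;
        const double gxh = gact * ga;
        s1 += gxh;
        s2 += gxh * xh[k];
      }
    }
    ggamma[c] = sgg; gbeta[c] = sgb;
    for (int b = 0; b < B; ++b) {
      const double* gg = g.begin() + HW * (c + (size_t)b * C);
      const double* xh = xhat.begin() + HW * (c + (size_t)b * C);
      double* gzp = gz.begin() + HW * (c + (size_t)b * C);
      for (size_t k = 0; k < HW; ++k) {
        const double ybn = ga * xh[k] + be;
        const double gact = ybn < 0 ? gg[k] * slope : gg[k];
        const double gxh = gact * ga;
        gzp[k] = training ? is * (gxh - s1 / n - xh[k] * s2 / n)
                          : is * gxh;
      }
    }
  }
  return List::create(_["gz"] = gz, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---- batched message passing over all topology pairs ----
// sph:  softplus-rectified downsampled heatmaps [h, w, L, B]
// spk:  softplus-rectified upsampled kernels    [2h, 2w, P]
// spb:  softplus-rectified biases               [h, w, P]
// ii/jj: 1-based receiver/sender landmark per pair
// Returns the per-receiver log-message sums S [h, w, L, B] and the cached
// pre-log terms inners [h, w, B, P].

// [[Rcpp::export]]
List cpp_msg_all_fwd(NumericVector sph, NumericVector spk, NumericVector spb,
                     IntegerVector ii, IntegerVector jj, double eps) {
  IntegerVector d = sph.attr("dim");
  const int h = d[0], w = d[1], L = d[2], B = d[3];
  const int P = ii.size();
  const size_t N = (size_t)h * w;
  NumericVector S = make4(h, w, L, B);
  NumericVector inners = make4_raw(h, w, B, P);
  arma::mat M(N, N);
  arma::mat X(N, B), Y(N, B);
  for (int p = 0; p < P; ++p) {
    arma::mat Km(spk.begin() + (size_t)p * 4 * N, 2 * h, 2 * w, false, true);
    M = msg_toeplitz(Km, h, w);
    const int j = jj[p] - 1, i = ii[p] - 1;
    for (int b = 0; b < B; ++b)
      std::copy(sph.begin() + N * (j + (size_t)b * L),
                sph.begin() + N * (j + (size_t)b * L) + N, X.colptr(b));
    Y = M * X;
    const double* bb = spb.begin() + (size_t)p * N;
    double* inn = inners.begin() + (size_t)p * N * B;
    for (int b = 0; b < B; ++b) {
      double* Sp = S.begin() + N * (i + (size_t)b * L);
      const double* Yp = Y.colptr(b);
      double* ip = inn + (size_t)b * N;
      for (size_t k = 0; k < N; ++k) {
        const double v = Yp[k] + bb[k] + eps;
        ip[k] = v;
        Sp[k] += std::log(v);
      }
    }
  }
  return List::create(_["S"] = S, _["inners"] = inners);
}

// [[Rcpp::export]]
List cpp_msg_all_bwd(NumericVector sph, NumericVector spk, NumericVector gS,
                     NumericVector inners, IntegerVector ii, IntegerVector jj) {
  IntegerVector d = sph.attr("dim");
  const int h = d[0], w = d[1], L = d[2], B = d[3];
  const int P = ii.size();
  const size_t N = (size_t)h * w;
  NumericVector gsph = make4(h, w, L, B);
  NumericVector gkup(R_xlen_t(4 * N * P));
  gkup.attr("dim") = IntegerVector::create(2 * h, 2 * w, P);
  NumericVector gbias(R_xlen_t(N * P));
  gbias.attr("dim") = IntegerVector::create(h, w, P);
  arma::mat M(N, N), dM(N, N);
  arma::mat X(N, B), G(N, B), GH(N, B);
  for (int p = 0; p < P; ++p) {
    arma::mat Km(spk.begin() + (size_t)p * 4 * N, 2 * h, 2 * w, false, true);
    M = msg_toeplitz(Km, h, w);
    const int j = jj[p] - 1, i = ii[p] - 1;
    const double* inn = inners.begin() + (size_t)p * N * B;
    double* gb = gbias.begin() + (size_t)p * N;
    for (int b = 0; b < B; ++b) {
      const double* gSp = gS.begin() + N * (i + (size_t)b * L);
      const double* ip = inn + (size_t)b * N;
      double* Gp = G.colptr(b);
      for (size_t k = 0; k < N; ++k) {
        const double gi = gSp[k] / ip[k];
        Gp[k] = gi;
        gb[k] += gi;
      }
      std::copy(sph.begin() + N * (j + (size_t)b * L),
                sph.begin() + N * (j + (size_t)b * L) + N, X.colptr(b));
    }
    GH = M.t() * G;
    for (int b = 0; b < B; ++b) {
      double* dst = gsph.begin() + N * (j + (size_t)b * L);
      const double* src = GH.colptr(b);
      for (size_t k = 0; k < N; ++k) dst[k] += src[k];
    }
    dM = G * X.t();
    arma::mat gK(gkup.begin() + (size_t)p * 4 * N, 2 * h, 2 * w, false, true);
    for (int px = 0; px < w; ++px)
      for (int py = 0; py < h; ++py) {
        const int pp = py + px * h;
        for (int nx = 0; nx < w; ++nx) {
          double* kcol = gK.colptr(w + nx - px);
          const double* mcol = dM.colptr(pp) + (size_t)nx * h;
          for (int ny = 0; ny < h; ++ny) kcol[h + ny - py] += mcol[ny];
        }
      }
  }
  return List::create(_["gsph"] = gsph, _["gkup"] = gkup, _["gbias"] = gbias);
}


// ---- fused single-pass helpers (memory-bandwidth bound host) ----

// visibility-masked mean squared error over heatmap channels; one pass.
// vis is an L x B 0/1 matrix; N = H*W*sum(vis).
// [[Rcpp::export]]
List cpp_mse_loss(NumericVector pred, NumericVector target, NumericMatrix vis) {
  IntegerVector d = pred.attr("dim");
  const int H = d[0], W = d[1], L = d[2], B = d[3];
  const size_t HW = (size_t)H * W;
  double nvis = 0;
  for (int b = 0; b < B; ++b) for (int l = 0; l < L; ++l) nvis += vis(l, b);
  NumericVector grad = make4(H, W, L, B);
  if (nvis == 0) return List::create(_["loss"] = 0.0, _["grad"] = grad);
  const double N = HW * nvis;
  double loss = 0;
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l) {
      if (vis(l, b) == 0) continue;
      const double* p = pred.begin() + HW * (l + (size_t)b * L);
      const double* t = target.begin() + HW * (l + (size_t)b * L);
      double* g = grad.begin() + HW * (l + (size_t)b * L);
      double acc = 0;
      for (size_t k = 0; k < HW; ++k) {
        const double df = p[k] - t[k];
        acc += df * df;
        g[k] = 2.0 * df / N;
      }
      loss += acc;
    }
  return List::create(_["loss"] = loss / N, _["grad"] = grad);
}

// softmax soft-argmax over each channel/batch slice; returns expected (u, v)
// coordinates and the softmax probabilities for backprop.
// [[Rcpp::export]]
List cpp_dsnt_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], L = d[2], B = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector p = make4_raw(H, W, L, B);
  NumericVector coords(R_xlen_t((size_t)L * 2 * B));
  coords.attr("dim") = IntegerVector::create(L, 2, B);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l) {
      const double* xs = x.begin() + HW * (l + (size_t)b * L);
      double* ps = p.begin() + HW * (l + (size_t)b * L);
      double mx = xs[0];
      for (size_t k = 1; k < HW; ++k) if (xs[k] > mx) mx = xs[k];
      double sum = 0;
      for (size_t k = 0; k < HW; ++k) { ps[k] = std::exp(xs[k] - mx); sum += ps[k]; }
      double eu = 0, ev = 0;
      const double inv = 1.0 / sum;
      for (int cx = 0; cx < W; ++cx) {
        const double* col = ps + (size_t)cx * H;
        double cs = 0, vs = 0;
        for (int cy = 0; cy < H; ++cy) { cs += col[cy]; vs += col[cy] * cy; }
        eu += cs * cx; ev += vs;
      }
      for (size_t k = 0; k < HW; ++k) ps[k] *= inv;
      coords[l + (size_t)0 * L + (size_t)b * 2 * L] = eu * inv;
      coords[l + (size_t)1 * L + (size_t)b * 2 * L] = ev * inv;
    }
  return List::create(_["coords"] = coords, _["p"] = p);
}

// [[Rcpp::export]]
NumericVector cpp_dsnt_bwd(NumericVector p, NumericVector coords,
                           NumericVector gcoords) {
  IntegerVector d = p.attr("dim");
  const int H = d[0], W = d[1], L = d[2], B = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector dz = make4_raw(H, W, L, B);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l) {
      const double* ps = p.begin() + HW * (l + (size_t)b * L);
      double* gz = dz.begin() + HW * (l + (size_t)b * L);
      const double eu = coords[l + (size_t)b * 2 * L];
      const double ev = coords[l + L + (size_t)b * 2 * L];
      const double gu = gcoords[l + (size_t)b * 2 * L];
      const double gv = gcoords[l + L + (size_t)b * 2 * L];
      for (int cx = 0; cx < W; ++cx) {
        const double* col = ps + (size_t)cx * H;
        double* gcol = gz + (size_t)cx * H;
        const double du = (cx - eu) * gu;
        for (int cy = 0; cy < H; ++cy)
          gcol[cy] = col[cy] * (du + (cy - ev) * gv);
      }
    }
  return dz;
}

// render the target blob stack for one image into a zeroed array; blobs are
// evaluated inside a cutoff x sigma box (tails beyond are below double
// rounding of the peak for the default cutoff).
static void render_targets_into(NumericMatrix co, LogicalVector vis,
                                int H, int W, double sigma, double gamma,
                                bool gaussian, double cutoff, double* out);

// [[Rcpp::export]]
NumericVector cpp_render_targets(NumericMatrix co, LogicalVector vis,
                                 int H, int W, double sigma, double gamma,
                                 bool gaussian, double cutoff = 8.0) {
  const int L = co.nrow();
  NumericVector y(R_xlen_t((size_t)H * W * L));
  y.attr("dim") = IntegerVector::create(H, W, L);
  render_targets_into(co, vis, H, W, sigma, gamma, gaussian, cutoff, y.begin());
  return y;
}

// render one image's blob stack directly into slice b of a [H,W,L,B] slab
// (slab must arrive zeroed where untouched; we zero the slice ourselves).
// [[Rcpp::export]]
NumericVector cpp_render_targets_slab(NumericVector slab, NumericMatrix co,
                                      LogicalVector vis, int b, double sigma,
                                      double gamma, bool gaussian,
                                      double cutoff = 8.0) {
  IntegerVector d = slab.attr("dim");
  const int H = d[0], W = d[1], L = d[2];
  double* dst = slab.begin() + (size_t)(b - 1) * H * W * L;
  std::fill(dst, dst + (size_t)H * W * L, 0.0);
  render_targets_into(co, vis, H, W, sigma, gamma, gaussian, cutoff, dst);
  return slab;
}

static void render_targets_into(NumericMatrix co, LogicalVector vis,
                                int H, int W, double sigma, double gamma,
                                bool gaussian, double cutoff, double* out) {
  const int L = co.nrow();
  const double r = cutoff * sigma * (gaussian ? 1.0 : 2.5);
  for (int l = 0; l < L; ++l) {
    if (!vis[l]) continue;
    const double u = co(l, 0), v = co(l, 1);
    const int x0 = std::max(0, (int)std::floor(u - r)),
              x1 = std::min(W - 1, (int)std::ceil(u + r)),
              y0 = std::max(0, (int)std::floor(v - r)),
              y1 = std::min(H - 1, (int)std::ceil(v + r));
    double* ch = out + (size_t)l * H * W;
    for (int cx = x0; cx <= x1; ++cx) {
      double* col = ch + (size_t)cx * H;
      const double du2 = (cx - u) * (cx - u);
      for (int cy = y0; cy <= y1; ++cy) {
        const double d2 = du2 + (cy - v) * (cy - v);
        col[cy] = gaussian ? gamma * std::exp(-d2 / (2 * sigma * sigma))
                           : gamma * std::exp(-std::sqrt(d2) / sigma);
      }
    }
  }
}

static inline double softplus_b(double x, double beta) {
  const double bx = beta * x;
  return (bx > 0 ? x : 0.0) + std::log1p(std::exp(-std::fabs(bx))) / beta;
}

// fused marginal-energy assembly: mehat = log(softplus_beta(p + eps)) + Sup
// [[Rcpp::export]]
NumericVector cpp_me_fwd(NumericVector p, NumericVector Sup, double beta,
                         double eps) {
  NumericVector out(no_init(p.size()));
  out.attr("dim") = p.attr("dim");
  const double* pp = p.begin(); const double* ss = Sup.begin();
  double* oo = out.begin();
  const R_xlen_t n = p.size();
  for (R_xlen_t k = 0; k < n; ++k)
    oo[k] = std::log(softplus_b(pp[k] + eps, beta)) + ss[k];
  return out;
}

// gradient of log softplus_beta(p + eps) term: gme * sigmoid(beta (p+eps)) / sp
// [[Rcpp::export]]
NumericVector cpp_me_bwd(NumericVector p, NumericVector gme, double beta,
                         double eps) {
  NumericVector out(no_init(p.size()));
  out.attr("dim") = p.attr("dim");
  const double* pp = p.begin(); const double* gg = gme.begin();
  double* oo = out.begin();
  const R_xlen_t n = p.size();
  for (R_xlen_t k = 0; k < n; ++k) {
    const double x = pp[k] + eps;
    const double sig = 1.0 / (1.0 + std::exp(-beta * x));
    oo[k] = gg[k] * sig / softplus_b(x, beta);
  }
  return out;
}


// backward-warp bilinear sampling: out(y,x) = img(sv(y,x), su(y,x)), zero
// outside the frame (coordinates are 0-based (u, v) = (col, row)).
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix img, NumericMatrix su,
                                NumericMatrix sv) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      const double u = su(y, x), v = sv(y, x);
      const int u0 = (int)std::floor(u), v0 = (int)std::floor(v);
      const double fu = u - u0, fv = v - v0;
      double acc = 0;
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          const int uu = u0 + dx, vv = v0 + dy;
          if (uu < 0 || uu >= W || vv < 0 || vv >= H) continue;
          acc += img(vv, uu) * (dx ? fu : 1 - fu) * (dy ? fv : 1 - fv);
        }
      out(y, x) = acc;
    }
  return out;
}
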