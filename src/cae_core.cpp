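// Fused single-precision forward/backward pass of the convolutional
// autoencoder, used by the trainers and the adaptation objectives where
// throughput on one CPU matters. Parameters cross the R boundary as double
// arrays (the package's canonical representation); activations and GEMMs
// run in float. The R-level double implementation in R/cae.R is the
// reference; both paths share layouts and the synergy-rearrangement
// convention, and agree to single precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

struct ConvLayer {
  int kh, kw, ci, co;   // array dims (kh, kw, ci, co)
  std::vector<fmat> Wk; // kh==1: per-kwi (ci x co) slices
  fmat Wm;              // kh>1: (kh*kw*ci x co)
  fvec b;
};

ConvLayer load_layer(const List& lay) {
  ConvLayer L;
  NumericVector w = lay["w"];
  NumericVector b = lay["b"];
  IntegerVector d = w.attr("dim");
  L.kh = d[0]; L.kw = d[1]; L.ci = d[2]; L.co = d[3];
  L.b = fvec(b.size());
  for (int i = 0; i < (int)b.size(); ++i) L.b[i] = (float)b[i];
  if (L.kh == 1) {
    L.Wk.resize(L.kw);
    for (int kwi = 0; kwi < L.kw; ++kwi) {
      fmat M(L.ci, L.co);
      for (int oc = 0; oc < L.co; ++oc)
        for (int ic = 0; ic < L.ci; ++ic)
          M(ic, oc) = (float)w[kwi + L.kw * ic + (size_t)L.kw * L.ci * oc];
      L.Wk[kwi] = M;
    }
  } else {
    size_t K = (size_t)L.kh * L.kw * L.ci;
    L.Wm.set_size(K, L.co);
    for (int oc = 0; oc < L.co; ++oc)
      for (size_t k = 0; k < K; ++k)
        L.Wm(k, oc) = (float)w[k + K * oc];
  }
  return L;
}

// Batched activation: (H*W, C) per image, images stacked along columns in
// blocks: full matrix (H*W, C*B) with image b occupying cols [b*C, (b+1)*C).
struct Act {
  int H, W, C, B;
  fmat m;
  void init(int H_, int W_, int C_, int B_) {
    H = H_; W = W_; C = C_; B = B_;
    m.set_size((size_t)H * W, (size_t)C * B);
  }
  fmat img(int b) { return m.cols((size_t)b * C, (size_t)(b + 1) * C - 1); }
};

inline void lrelu_ip(fmat& a) { a = 0.55f * a + 0.45f * arma::abs(a); }

// gy *= slope(y)
inline void lrelu_bwd_ip(fmat& gy, const fmat& y) {
  gy = gy % (0.55f + 0.45f * arma::sign(y));
}

// Temporal convolution y = conv1d(x) + b (valid along W, kernel 1 x kw).
void conv1d_fwd(Act& x, const ConvLayer& L, Act& y) {
  int OW = x.W - L.kw + 1, P = x.H * OW;
  y.init(x.H, OW, L.co, x.B);
  for (int b = 0; b < x.B; ++b) {
    fmat X = x.m.cols((size_t)b * x.C, (size_t)(b + 1) * x.C - 1);
    fmat Y(P, L.co);
    Y.each_row() = L.b.t();
    for (int kwi = 0; kwi < L.kw; ++kwi) {
      Y += X.rows((size_t)x.H * kwi, (size_t)x.H * kwi + P - 1) * L.Wk[kwi];
    }
    y.m.cols((size_t)b * L.co, (size_t)(b + 1) * L.co - 1) = Y;
  }
}

// Backward of conv1d: gx (optional), gw (kw slices ci x co), gb.
void conv1d_bwd(Act& x, const ConvLayer& L, Act& gy,
                bool need_gx, Act& gx, std::vector<fmat>& gw, fvec& gb) {
  int P = x.H * gy.W;
  gw.assign(L.kw, fmat(L.ci, L.co, arma::fill::zeros));
  gb.zeros(L.co);
  if (need_gx) {
    gx.init(x.H, x.W, x.C, x.B);
    gx.m.zeros();
  }
  for (int b = 0; b < x.B; ++b) {
    fmat X = x.m.cols((size_t)b * x.C, (size_t)(b + 1) * x.C - 1);
    fmat Gy = gy.m.cols((size_t)b * L.co, (size_t)(b + 1) * L.co - 1);
    gb += arma::sum(Gy, 0).t();
    for (int kwi = 0; kwi < L.kw; ++kwi) {
      gw[kwi] += X.rows((size_t)x.H * kwi, (size_t)x.H * kwi + P - 1).t() * Gy;
      if (need_gx) {
        gx.m.submat((size_t)x.H * kwi, (size_t)b * x.C,
                    (size_t)x.H * kwi + P - 1, (size_t)(b + 1) * x.C - 1) +=
          Gy * L.Wk[kwi].t();
      }
    }
  }
}

// Temporal transposed convolution, layer array dims (1, kw, co, ci):
// input ci maps (narrow), output co maps (wide).
void tconv1d_fwd(Act& x, const ConvLayer& L, Act& y) {
  // L.ci here is the wide (output) side per load_layer dims (kh,kw,co,ci):
  // array third dim = co_t (output maps), fourth = ci_t (input maps)
  int co_t = L.ci, ci_t = L.co;
  int OW = x.W + L.kw - 1, P = x.H * x.W;
  y.init(x.H, OW, co_t, x.B);
  for (int b = 0; b < x.B; ++b) {
    fmat X = x.m.cols((size_t)b * ci_t, (size_t)(b + 1) * ci_t - 1);
    fmat Y((size_t)x.H * OW, co_t, arma::fill::zeros);
    for (int kwi = 0; kwi < L.kw; ++kwi) {
      Y.rows((size_t)x.H * kwi, (size_t)x.H * kwi + P - 1) += X * L.Wk[kwi].t();
    }
    Y.each_row() += L.b.t();
    y.m.cols((size_t)b * co_t, (size_t)(b + 1) * co_t - 1) = Y;
  }
}

void tconv1d_bwd(Act& x, const ConvLayer& L, Act& gy,
                 Act& gx, std::vector<fmat>& gw, fvec& gb) {
  int co_t = L.ci, ci_t = L.co;
  int P = x.H * x.W;
  gw.assign(L.kw, fmat(co_t, ci_t, arma::fill::zeros));
  gb.zeros(co_t);
  gx.init(x.H, x.W, ci_t, x.B);
  gx.m.zeros();
  for (int b = 0; b < x.B; ++b) {
    fmat X = x.m.cols((size_t)b * ci_t, (size_t)(b + 1) * ci_t - 1);
    fmat Gy = gy.m.cols((size_t)b * co_t, (size_t)(b + 1) * co_t - 1);
    gb += arma::sum(Gy, 0).t();
    fmat GX = gx.m.cols((size_t)b * ci_t, (size_t)(b + 1) * ci_t - 1);
    for (int kwi = 0; kwi < L.kw; ++kwi) {
      fmat Gslice = Gy.rows((size_t)x.H * kwi, (size_t)x.H * kwi + P - 1);
      gw[kwi] += Gslice.t() * X;
      GX += Gslice * L.Wk[kwi];
    }
    gx.m.cols((size_t)b * ci_t, (size_t)(b + 1) * ci_t - 1) = GX;
  }
}

void im2col_f(const fmat& X, int H, int W, int C, int kh, int kw,
              int OH, int OW, fmat& col) {
  col.set_size((size_t)kh * kw * C, (size_t)OH * OW);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      float* dst = col.colptr((size_t)oh + (size_t)OH * ow);
      for (int ic = 0; ic < C; ++ic) {
        const float* xc = X.colptr(ic) + (size_t)ow * H + oh;
        for (int kwi = 0; kwi < kw; ++kwi) {
          const float* src = xc + (size_t)kwi * H;
          for (int khi = 0; khi < kh; ++khi) *dst++ = src[khi];
        }
      }
    }
  }
}

void col2im_f(const fmat& col, int H, int W, int C, int kh, int kw,
              int OH, int OW, fmat& X) {
  X.zeros((size_t)H * W, C);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const float* src = col.colptr((size_t)oh + (size_t)OH * ow);
      for (int ic = 0; ic < C; ++ic) {
        float* xc = X.colptr(ic) + (size_t)ow * H + oh;
        for (int kwi = 0; kwi < kw; ++kwi) {
          float* dst = xc + (size_t)kwi * H;
          for (int khi = 0; khi < kh; ++khi) dst[khi] += *src++;
        }
      }
    }
  }
}

// 2-D convolution (4x4 layers), standard direction.
void conv2d_fwd(Act& x, const ConvLayer& L, Act& y) {
  int OH = x.H - L.kh + 1, OW = x.W - L.kw + 1;
  y.init(OH, OW, L.co, x.B);
  fmat col;
  for (int b = 0; b < x.B; ++b) {
    fmat X = x.m.cols((size_t)b * x.C, (size_t)(b + 1) * x.C - 1);
    im2col_f(X, x.H, x.W, x.C, L.kh, L.kw, OH, OW, col);
    fmat Y = col.t() * L.Wm;
    Y.each_row() += L.b.t();
    y.m.cols((size_t)b * L.co, (size_t)(b + 1) * L.co - 1) = Y;
  }
}

void conv2d_bwd(Act& x, const ConvLayer& L, Act& gy, bool need_gx,
                Act& gx, fmat& gw, fvec& gb) {
  int OH = gy.H, OW = gy.W;
  gw.zeros(L.Wm.n_rows, L.Wm.n_cols);
  gb.zeros(L.co);
  if (need_gx) {
    gx.init(x.H, x.W, x.C, x.B);
  }
  fmat col;
  for (int b = 0; b < x.B; ++b) {
    fmat X = x.m.cols((size_t)b * x.C, (size_t)(b + 1) * x.C - 1);
    fmat Gy = gy.m.cols((size_t)b * L.co, (size_t)(b + 1) * L.co - 1);
    gb += arma::sum(Gy, 0).t();
    im2col_f(X, x.H, x.W, x.C, L.kh, L.kw, OH, OW, col);
    gw += col * Gy;
    if (need_gx) {
      fmat colg = L.Wm * Gy.t();
      fmat GX;
      col2im_f(colg, x.H, x.W, x.C, L.kh, L.kw, OH, OW, GX);
      gx.m.cols((size_t)b * x.C, (size_t)(b + 1) * x.C - 1) = GX;
    }
  }
}

// 2-D transposed convolution, layer array dims (kh, kw, co, ci).
void tconv2d_fwd(Act& x, const ConvLayer& L, Act& y) {
  int co_t = L.ci, ci_t = L.co;
  int OH = x.H + L.kh - 1, OW = x.W + L.kw - 1;
  y.init(OH, OW, co_t, x.B);
  fmat colg, Y;
  for (int b = 0; b < x.B; ++b) {
    fmat X = x.m.cols((size_t)b * ci_t, (size_t)(b + 1) * ci_t - 1);
    colg = L.Wm * X.t(); // (kh*kw*co_t x P_in)
    col2im_f(colg, OH, OW, co_t, L.kh, L.kw, x.H, x.W, Y);
    Y.each_row() += L.b.t();
    y.m.cols((size_t)b * co_t, (size_t)(b + 1) * co_t - 1) = Y;
  }
}

void tconv2d_bwd(Act& x, const ConvLayer& L, Act& gy,
                 Act& gx, fmat& gw, fvec& gb) {
  int co_t = L.ci, ci_t = L.co;
  gw.zeros(L.Wm.n_rows, L.Wm.n_cols);
  gb.zeros(co_t);
  gx.init(x.H, x.W, ci_t, x.B);
  fmat col;
  for (int b = 0; b < x.B; ++b) {
    fmat X = x.m.cols((size_t)b * ci_t, (size_t)(b + 1) * ci_t - 1);
    fmat Gy = gy.m.cols((size_t)b * co_t, (size_t)(b + 1) * co_t - 1);
    gb += arma::sum(Gy, 0).t();
    im2col_f(Gy, gy.H, gy.W, co_t, L.kh, L.kw, x.H, x.W, col);
    gw += col * X;
    gx.m.cols((size_t)b * ci_t, (size_t)(b + 1) * ci_t - 1) = col.t() * L.Wm;
  }
}

// Permute the channel-row axis (H) of maps in 5 groups: out row r = in row
// perm[r] (1-based perms from R).
void rearrange_f(Act& a, const IntegerMatrix& orders, bool inverse) {
  int n_groups = orders.nrow();
  int per = a.C / n_groups;
  fmat out((size_t)a.H * a.W, a.C);
  std::vector<int> perm(a.H);
  for (int b = 0; b < a.B; ++b) {
    fmat X = a.m.cols((size_t)b * a.C, (size_t)(b + 1) * a.C - 1);
    for (int g = 0; g < n_groups; ++g) {
      for (int r = 0; r < a.H; ++r) {
        int p = orders(g, r) - 1;
        if (inverse) perm[p] = r; else perm[r] = p;
      }
      for (int c = g * per; c < (g + 1) * per; ++c) {
        for (int w = 0; w < a.W; ++w) {
          for (int r = 0; r < a.H; ++r) {
            out((size_t)r + (size_t)a.H * w, c) =
              X((size_t)perm[r] + (size_t)a.H * w, c);
          }
        }
      }
    }
    a.m.cols((size_t)b * a.C, (size_t)(b + 1) * a.C - 1) = out;
  }
}

NumericVector wrap_grad_1d(const std::vector<fmat>& gw, int kh, int kw,
                           int ci, int co) {
  NumericVector out((size_t)kh * kw * ci * co);
  out.attr("dim") = IntegerVector::create(kh, kw, ci, co);
  for (int oc = 0; oc < co; ++oc)
    for (int ic = 0; ic < ci; ++ic)
      for (int kwi = 0; kwi < kw; ++kwi)
        out[kwi + kw * ic + (size_t)kw * ci * oc] = gw[kwi](ic, oc);
  return out;
}

NumericVector wrap_grad_2d(const fmat& gw, int kh, int kw, int ci, int co) {
  NumericVector out((size_t)kh * kw * ci * co);
  out.attr("dim") = IntegerVector::create(kh, kw, ci, co);
  size_t K = (size_t)kh * kw * ci;
  for (int oc = 0; oc < co; ++oc)
    for (size_t k = 0; k < K; ++k) out[k + K * oc] = gw(k, oc);
  return out;
}

NumericVector wrap_bias(const fvec& gb) {
  NumericVector out(gb.n_elem);
  for (size_t i = 0; i < gb.n_elem; ++i) out[i] = gb[i];
  return out;
}

List grad_entry(NumericVector w, NumericVector b) {
  return List::create(Named("w") = w, Named("b") = b);
}

} // namespace

// Fused forward(+backward) pass. enc/dec: lists of 5 layers (w, b).
// orders: 5 x 9 integer matrix of 1-based channel permutations.
// x: (9, 200, B) or (9, 200, 1, B) double array.
// If grads = TRUE, returns the gradients of mean((recon - x)^2) w.r.t. all
// parameters (encoder layers 1-3 only when deep = TRUE).
// [[Rcpp::export(name = ".cae_fused_cpp")]]
List cae_fused_cpp(List enc, List dec, IntegerMatrix orders, NumericVector x,
                   bool grads, bool deep, bool want_recon,
                   bool want_feature) {
  IntegerVector xd = x.attr("dim");
  int B = xd[xd.size() - 1];
  std::vector<ConvLayer> E(5), D(5);
  for (int i = 0; i < 5; ++i) {
    E[i] = load_layer(enc[i]);
    D[i] = load_layer(dec[i]);
  }
  Act a0; a0.init(9, 200, 1, B);
  for (size_t i = 0; i < (size_t)1800 * B; ++i) {
    a0.m[i] = (float)x[i];
  }

  Act a1, a2, a3, a4, feat, d1, d2, d3, d4, rec;
  conv1d_fwd(a0, E[0], a1); lrelu_ip(a1.m);
  conv1d_fwd(a1, E[1], a2); lrelu_ip(a2.m);
  conv1d_fwd(a2, E[2], a3); lrelu_ip(a3.m);
  rearrange_f(a3, orders, false); // a3 now holds the rearranged maps
  conv2d_fwd(a3, E[3], a4); lrelu_ip(a4.m);
  conv2d_fwd(a4, E[4], feat);
  tconv2d_fwd(feat, D[0], d1); lrelu_ip(d1.m);
  tconv2d_fwd(d1, D[1], d2); lrelu_ip(d2.m);
  rearrange_f(d2, orders, true);
  tconv1d_fwd(d2, D[2], d3); lrelu_ip(d3.m);
  tconv1d_fwd(d3, D[3], d4); lrelu_ip(d4.m);
  tconv1d_fwd(d4, D[4], rec);

  size_t N = (size_t)1800 * B;
  fmat diff = rec.m - a0.m;
  double loss = (double)arma::accu(arma::square(diff)) / (double)N;

  List out = List::create(Named("loss") = loss);
  if (want_recon) {
    NumericVector rv(N);
    rv.attr("dim") = IntegerVector::create(9, 200, B);
    for (size_t i = 0; i < N; ++i) rv[i] = rec.m[i];
    out["recon"] = rv;
  }
  if (want_feature) {
    // feature Act: (3, 7, 40, B) -> (3, 7, 40, B) double array
    NumericVector fv((size_t)3 * 7 * 40 * B);
    fv.attr("dim") = IntegerVector::create(3, 7, 40, B);
    for (size_t i = 0; i < (size_t)3 * 7 * 40 * B; ++i) fv[i] = feat.m[i];
    out["feature"] = fv;
  }
  if (!grads) return out;

  // backward
  Act g; g.init(9, 200, 1, B);
  g.m = (2.0f / (float)N) * diff;
  Act gd4, gd3, gd2, gd1, gfeat, ga4, ga3, ga2, ga1, gx_unused;
  std::vector<fmat> gw1d; fmat gw2d; fvec gb;
  List dec_g(5), enc_g(5);

  tconv1d_bwd(d4, D[4], g, gd4, gw1d, gb);
  dec_g[4] = grad_entry(wrap_grad_1d(gw1d, 1, D[4].kw, D[4].ci, D[4].co), wrap_bias(gb));
  lrelu_bwd_ip(gd4.m, d4.m);
  tconv1d_bwd(d3, D[3], gd4, gd3, gw1d, gb);
  dec_g[3] = grad_entry(wrap_grad_1d(gw1d, 1, D[3].kw, D[3].ci, D[3].co), wrap_bias(gb));
  lrelu_bwd_ip(gd3.m, d3.m);
  tconv1d_bwd(d2, D[2], gd3, gd2, gw1d, gb);
  dec_g[2] = grad_entry(wrap_grad_1d(gw1d, 1, D[2].kw, D[2].ci, D[2].co), wrap_bias(gb));
  rearrange_f(gd2, orders, false); // adjoint of inverse rearrangement
  // d2 was un-rearranged in place; restore rearranged copy for the mask
  rearrange_f(d2, orders, false);
  lrelu_bwd_ip(gd2.m, d2.m);
  tconv2d_bwd(d1, D[1], gd2, gd1, gw2d, gb);
  dec_g[1] = grad_entry(wrap_grad_2d(gw2d, D[1].kh, D[1].kw, D[1].ci, D[1].co), wrap_bias(gb));
  lrelu_bwd_ip(gd1.m, d1.m);
  tconv2d_bwd(feat, D[0], gd1, gfeat, gw2d, gb);
  dec_g[0] = grad_entry(wrap_grad_2d(gw2d, D[0].kh, D[0].kw, D[0].ci, D[0].co), wrap_bias(gb));

  conv2d_bwd(a4, E[4], gfeat, true, ga4, gw2d, gb);
  enc_g[4] = grad_entry(wrap_grad_2d(gw2d, E[4].kh, E[4].kw, E[4].ci, E[4].co), wrap_bias(gb));
  lrelu_bwd_ip(ga4.m, a4.m);
  conv2d_bwd(a3, E[3], ga4, deep, ga3, gw2d, gb);
  enc_g[3] = grad_entry(wrap_grad_2d(gw2d, E[3].kh, E[3].kw, E[3].ci, E[3].co), wrap_bias(gb));
  if (deep) {
    rearrange_f(ga3, orders, true); // adjoint of rearrangement
    rearrange_f(a3, orders, true);  // back to pre-rearranged maps for mask
    lrelu_bwd_ip(ga3.m, a3.m);
    conv1d_bwd(a2, E[2], ga3, true, ga2, gw1d, gb);
    enc_g[2] = grad_entry(wrap_grad_1d(gw1d, 1, E[2].kw, E[2].ci, E[2].co), wrap_bias(gb));
    lrelu_bwd_ip(ga2.m, a2.m);
    conv1d_bwd(a1, E[1], ga2, true, ga1, gw1d, gb);
    enc_g[1] = grad_entry(wrap_grad_1d(gw1d, 1, E[1].kw, E[1].ci, E[1].co), wrap_bias(gb));
    lrelu_bwd_ip(ga1.m, a1.m);
    conv1d_bwd(a0, E[0], ga1, false, gx_unused, gw1d, gb);
    enc_g[0] = grad_entry(wrap_grad_1d(gw1d, 1, E[0].kw, E[0].ci, E[0].co), wrap_bias(gb));
  } else {
    enc_g[0] = enc_g[1] = enc_g[2] = R_NilValue;
  }
  out["enc_grads"] = enc_g;
  out["dec_grads"] = dec_g;
  return out;
}
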