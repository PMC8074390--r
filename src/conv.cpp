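// Batched valid (no padding, stride 1) 2-D convolution primitives used by the
// convolutional autoencoder. Arrays follow the package's column-major layout:
//   activations: dim (H, W, C, B)   -- H = sEMG channel axis, W = time axis
//   filters:     dim (kh, kw, Cin, Cout)
// Transposed convolutions are expressed in R on top of conv_bwd_input /
// conv_bwd_filter (the adjoint pair of conv_fwd).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dim4(const NumericVector& a, int d[4]) {
  IntegerVector dm = a.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// col matrix: K x P with K = kh*kw*Cin (khi fastest, then kwi, then ic)
// and P = OH*OW (oh fastest). This matches the column-major flattening of the
// first three filter dimensions, so the filter array can be used as a K x Cout
// matrix without copying.
// Column-by-column fill: each col column (one output position) is written
// contiguously; the source image is small enough to stay cached.
static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, int OH, int OW, arma::mat& col) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      double* dst = col.colptr((size_t)oh + (size_t)OH * ow);
      for (int ic = 0; ic < Cin; ++ic) {
        const double* xc = x + (size_t)ic * H * W + (size_t)ow * H + oh;
        for (int kwi = 0; kwi < kw; ++kwi) {
          const double* src = xc + (size_t)kwi * H;
          for (int khi = 0; khi < kh; ++khi) {
            *dst++ = src[khi];
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& col, int H, int W, int Cin,
                       int kh, int kw, int OH, int OW, double* x) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const double* src = col.colptr((size_t)oh + (size_t)OH * ow);
      for (int ic = 0; ic < Cin; ++ic) {
        double* xc = x + (size_t)ic * H * W + (size_t)ow * H + oh;
        for (int kwi = 0; kwi < kw; ++kwi) {
          double* dst = xc + (size_t)kwi * H;
          for (int khi = 0; khi < kh; ++khi) {
            dst[khi] += *src++;
          }
        }
      }
    }
  }
}

// Extract the (Cin x Cout) weight slice for one kernel offset (khi, kwi).
static arma::mat weight_slice(const double* w, int kh, int kw, int Cin,
                              int Cout, int khi, int kwi) {
  arma::mat Wk(Cin, Cout);
  for (int oc = 0; oc < Cout; ++oc) {
    for (int ic = 0; ic < Cin; ++ic) {
      Wk(ic, oc) = w[khi + kh * (kwi + kw * ic) + (size_t)kh * kw * Cin * oc];
    }
  }
  return Wk;
}

// Temporal (kh == 1) layers avoid im2col entirely: for each kernel offset
// kwi the needed input slice x[, kwi:(kwi+OW-1), ] is a contiguous row
// range of the (H*W x Cin) matrix view, so the convolution is kw cached
// GEMMs on views.

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
NumericVector conv_fwd_cpp(NumericVector x, NumericVector w,
                           Nullable<NumericVector> bias) {
  int dx[4], dw[4];
  get_dim4(x, dx); get_dim4(w, dw);
  int H = dx[0], W = dx[1], Cin = dx[2], B = dx[3];
  int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != Cin) stop("filter Cin mismatch");
  int OH = H - kh + 1, OW = W - kw + 1;
  if (OH < 1 || OW < 1) stop("kernel larger than input");
  size_t K = (size_t)kh * kw * Cin, P = (size_t)OH * OW;

  NumericVector y(P * Cout * B);
  y.attr("dim") = IntegerVector::create(OH, OW, Cout, B);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, P);
  arma::rowvec bv;
  bool has_b = bias.isNotNull();
  if (has_b) {
    NumericVector b(bias);
    if ((int)b.size() != Cout) stop("bias length mismatch");
    bv = arma::rowvec(b.begin(), Cout);
  }
  if (kh == 1) {
    std::vector<arma::mat> Wk(kw);
    for (int kwi = 0; kwi < kw; ++kwi) {
      Wk[kwi] = weight_slice(w.begin(), kh, kw, Cin, Cout, 0, kwi);
    }
    for (int b = 0; b < B; ++b) {
      arma::mat X(const_cast<double*>(x.begin()) + (size_t)b * H * W * Cin,
                  (size_t)H * W, Cin, false, true);
      arma::mat Y(y.begin() + (size_t)b * P * Cout, P, Cout, false, true);
      if (has_b) Y.each_row() = bv; else Y.zeros();
      for (int kwi = 0; kwi < kw; ++kwi) {
        Y += X.rows((size_t)H * kwi, (size_t)H * kwi + P - 1) * Wk[kwi];
      }
    }
    return y;
  }
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)b * H * W * Cin;
    im2col(xb, H, W, Cin, kh, kw, OH, OW, col);
    arma::mat Y(y.begin() + (size_t)b * P * Cout, P, Cout, false, true);
    Y = col.t() * Wm;
    if (has_b) Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd_input_cpp")]]
NumericVector conv_bwd_input_cpp(NumericVector gy, NumericVector w,
                                 int H, int W) {
  int dg[4], dw[4];
  get_dim4(gy, dg); get_dim4(w, dw);
  int OH = dg[0], OW = dg[1], Cout = dg[2], B = dg[3];
  int kh = dw[0], kw = dw[1], Cin = dw[2];
  if (dw[3] != Cout) stop("filter Cout mismatch");
  if (OH != H - kh + 1 || OW != W - kw + 1) stop("output size mismatch");
  size_t K = (size_t)kh * kw * Cin, P = (size_t)OH * OW;

  NumericVector dx((size_t)H * W * Cin * B);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  if (kh == 1) {
    std::vector<arma::mat> Wk(kw);
    for (int kwi = 0; kwi < kw; ++kwi) {
      Wk[kwi] = weight_slice(w.begin(), kh, kw, Cin, Cout, 0, kwi).t();
    }
    for (int b = 0; b < B; ++b) {
      arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)b * P * Cout,
                   P, Cout, false, true);
      arma::mat DX(dx.begin() + (size_t)b * H * W * Cin,
                   (size_t)H * W, Cin, false, true);
      for (int kwi = 0; kwi < kw; ++kwi) {
        DX.rows((size_t)H * kwi, (size_t)H * kwi + P - 1) += Gy * Wk[kwi];
      }
    }
    return dx;
  }
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat colg(K, P);
  for (int b = 0; b < B; ++b) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)b * P * Cout,
                 P, Cout, false, true);
    colg = Wm * Gy.t();
    col2im_acc(colg, H, W, Cin, kh, kw, OH, OW,
               dx.begin() + (size_t)b * H * W * Cin);
  }
  return dx;
}

// [[Rcpp::export(name = ".conv_bwd_filter_cpp")]]
NumericVector conv_bwd_filter_cpp(NumericVector x, NumericVector gy) {
  int dx[4], dg[4];
  get_dim4(x, dx); get_dim4(gy, dg);
  int H = dx[0], W = dx[1], Cin = dx[2], B = dx[3];
  int OH = dg[0], OW = dg[1], Cout = dg[2];
  if (dg[3] != B) stop("batch mismatch");
  int kh = H - OH + 1, kw = W - OW + 1;
  size_t K = (size_t)kh * kw * Cin, P = (size_t)OH * OW;

  NumericVector dwv(K * Cout);
  dwv.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  if (kh == 1) {
    arma::mat acc(Cin, Cout);
    for (int kwi = 0; kwi < kw; ++kwi) {
      acc.zeros();
      for (int b = 0; b < B; ++b) {
        arma::mat X(const_cast<double*>(x.begin()) + (size_t)b * H * W * Cin,
                    (size_t)H * W, Cin, false, true);
        arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)b * P * Cout,
                     P, Cout, false, true);
        acc += X.rows((size_t)H * kwi, (size_t)H * kwi + P - 1).t() * Gy;
      }
      for (int oc = 0; oc < Cout; ++oc) {
        for (int ic = 0; ic < Cin; ++ic) {
          dwv[kwi + kw * ic + (size_t)kw * Cin * oc] = acc(ic, oc);
        }
      }
    }
    return dwv;
  }
  arma::mat DW(dwv.begin(), K, Cout, false, true);
  arma::mat col(K, P);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * H * W * Cin, H, W, Cin, kh, kw, OH, OW, col);
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)b * P * Cout,
                 P, Cout, false, true);
    DW += col * Gy;
  }
  return dwv;
}
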