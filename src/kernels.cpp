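// Compiled kernels for 2-D convolution, transposed convolution and their
// gradients, via im2col / col2im plus BLAS matrix products.
//
// Tensor layout (R arrays, column-major): activations [H, W, C, N];
// convolution weights [kh, kw, Cin, Cout]; transposed-convolution weights
// [kh, kw, Cout, Cin].  The patch matrix `col` is laid out P x K with
// P = Ho*Wo spatial positions (row index j = wo*Ho + ho) and
// K = kh*kw*C taps (column index r = c*kh*kw + kj*kh + ki), so the
// innermost copy loops run over contiguous memory on both sides and the
// matrix products map onto single BLAS calls.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int range_lo(int k, int pad, int stride) {
  const int d = pad - k;
  return d <= 0 ? 0 : (d + stride - 1) / stride;
}

// Gather patches of x (H x W x C, one sample) into col (Ho*Wo x kh*kw*C).
static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, arma::mat& col) {
  col.zeros((arma::uword)Ho * Wo, (arma::uword)(kh * kw * C));
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      const int wo_lo = range_lo(kj, pad, stride);
      const int wo_hi = std::min(Wo - 1, (W - 1 + pad - kj) / stride);
      for (int ki = 0; ki < kh; ++ki) {
        const int ho_lo = range_lo(ki, pad, stride);
        const int ho_hi = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        if (wo_lo > wo_hi || ho_lo > ho_hi) continue;
        double* cr = col.colptr((arma::uword)(c * kh * kw + kj * kh + ki));
        for (int wo = wo_lo; wo <= wo_hi; ++wo) {
          const double* xw = xc + (size_t)(wo * stride - pad + kj) * H;
          double* dst = cr + (size_t)wo * Ho;
          if (stride == 1) {
            const double* src = xw - pad + ki;
            for (int ho = ho_lo; ho <= ho_hi; ++ho) dst[ho] = src[ho];
          } else {
            for (int ho = ho_lo; ho <= ho_hi; ++ho)
              dst[ho] = xw[ho * stride - pad + ki];
          }
        }
      }
    }
  }
}

// Scatter-add col (Ho*Wo x kh*kw*C) back into x (H x W x C, one sample).
static void col2im_one(const arma::mat& col, double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      const int wo_lo = range_lo(kj, pad, stride);
      const int wo_hi = std::min(Wo - 1, (W - 1 + pad - kj) / stride);
      for (int ki = 0; ki < kh; ++ki) {
        const int ho_lo = range_lo(ki, pad, stride);
        const int ho_hi = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        if (wo_lo > wo_hi || ho_lo > ho_hi) continue;
        const double* cr = col.colptr((arma::uword)(c * kh * kw + kj * kh + ki));
        for (int wo = wo_lo; wo <= wo_hi; ++wo) {
          double* xw = xc + (size_t)(wo * stride - pad + kj) * H;
          const double* src = cr + (size_t)wo * Ho;
          if (stride == 1) {
            double* dst = xw - pad + ki;
            for (int ho = ho_lo; ho <= ho_hi; ++ho) dst[ho] += src[ho];
          } else {
            for (int ho = ho_lo; ho <= ho_hi; ++ho)
              xw[ho * stride - pad + ki] += src[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()),
                     (arma::uword)kh * kw * Cin, (arma::uword)Cout, false, true);
  const arma::rowvec bv(const_cast<double*>(b.begin()), (arma::uword)Cout,
                        false, true);
  arma::mat col;
  const size_t xstep = (size_t)H * W * C, ystep = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + n * xstep, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat ym(y.begin() + n * ystep, (arma::uword)Ho * Wo, (arma::uword)Cout,
                 false, true);
    ym = col * Wm;
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad, bool need_gx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gw((R_xlen_t)w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((R_xlen_t)x.size());
    gx.attr("dim") = xd;
  }
  const arma::mat Wm(const_cast<double*>(w.begin()),
                     (arma::uword)kh * kw * C, (arma::uword)Cout, false, true);
  arma::mat gWm(gw.begin(), (arma::uword)kh * kw * C, (arma::uword)Cout,
                false, true);
  arma::vec gbv(gb.begin(), (arma::uword)Cout, false, true);
  arma::mat col, gcol;
  const size_t xstep = (size_t)H * W * C, ystep = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + n * xstep, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    const arma::mat gym(const_cast<double*>(gy.begin()) + n * ystep,
                        (arma::uword)Ho * Wo, (arma::uword)Cout, false, true);
    gWm += col.t() * gym;
    gbv += arma::sum(gym, 0).t();
    if (need_gx) {
      gcol = gym * Wm.t();
      col2im_one(gcol, gx.begin() + n * xstep, H, W, C, kh, kw, stride, pad,
                 Ho, Wo);
    }
  }
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_convt2d_fw(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int opad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[2], Cw = wd[3];
  if (Cw != Cin) stop("convt2d: input has %d channels, weight expects %d", Cin, Cw);
  const int Ho = (H - 1) * stride - 2 * pad + kh + opad;
  const int Wo = (W - 1) * stride - 2 * pad + kw + opad;
  if (Ho < 1 || Wo < 1) stop("convt2d: output size would be empty");
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()),
                     (arma::uword)kh * kw * Cout, (arma::uword)Cin, false, true);
  arma::mat gcol;
  const size_t xstep = (size_t)H * W * Cin, ystep = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    const arma::mat xm(const_cast<double*>(x.begin()) + n * xstep,
                       (arma::uword)H * W, (arma::uword)Cin, false, true);
    gcol = xm * Wm.t();
    double* yp = y.begin() + n * ystep;
    for (int c = 0; c < Cout; ++c)
      std::fill(yp + (size_t)c * Ho * Wo, yp + (size_t)(c + 1) * Ho * Wo, b[c]);
    col2im_one(gcol, yp, Ho, Wo, Cout, kh, kw, stride, pad, H, W);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int opad, bool need_gx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[2];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gw((R_xlen_t)w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((R_xlen_t)x.size());
    gx.attr("dim") = xd;
  }
  const arma::mat Wm(const_cast<double*>(w.begin()),
                     (arma::uword)kh * kw * Cout, (arma::uword)Cin, false, true);
  arma::mat gWm(gw.begin(), (arma::uword)kh * kw * Cout, (arma::uword)Cin,
                false, true);
  arma::vec gbv(gb.begin(), (arma::uword)Cout, false, true);
  arma::mat col;
  const size_t xstep = (size_t)H * W * Cin, ystep = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col_one(gy.begin() + n * ystep, Ho, Wo, Cout, kh, kw, stride, pad,
               H, W, col);
    const arma::mat xm(const_cast<double*>(x.begin()) + n * xstep,
                       (arma::uword)H * W, (arma::uword)Cin, false, true);
    const arma::mat gym(const_cast<double*>(gy.begin()) + n * ystep,
                        (arma::uword)Ho * Wo, (arma::uword)Cout, false, true);
    gWm += col.t() * xm;
    gbv += arma::sum(gym, 0).t();
    if (need_gx) {
      arma::mat gxm(gx.begin() + n * xstep, (arma::uword)H * W,
                    (arma::uword)Cin, false, true);
      gxm = col * Wm;
    }
  }
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gw, _["gb"] = gb);
}
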