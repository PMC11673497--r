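// Low-level tensor kernels for the super-resolution network.
//
// Layout convention: feature maps are R arrays of dim (H, W, C, B),
// column-major, so x[h, w, c, b] sits at h + H*(w + W*(c + C*b)).
// Convolution weights are (k, k, Cin, Cout); flattening the first three
// dims column-major matches the im2col column order used below, so the
// convolution reduces to one GEMM per image.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;

static void dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Fill M (Ho*Wo x k*k*Cin) with patches of one image (zero padding).
static void im2col(const double* xp, int H, int W, int Cin, int k,
                   int stride, int pad, int Ho, int Wo, mat& M) {
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xp + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* Mc = M.colptr(kh + k * (kw + k * ci));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          double* Mcw = Mc + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::fill(Mcw, Mcw + Ho, 0.0);
          } else {
            const double* xcw = xc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + kh;
              Mcw[ho] = (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
            }
          }
        }
      }
    }
  }
}

// Scatter-add the column matrix back onto one image (adjoint of im2col).
static void col2im_add(const mat& M, int H, int W, int Cin, int k,
                       int stride, int pad, int Ho, int Wo, double* gxp) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* gc = gxp + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* Mc = M.colptr(kh + k * (kw + k * ci));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          double* gcw = gc + (size_t)wi * H;
          const double* Mcw = Mc + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            if (hi >= 0 && hi < H) gcw[hi] += Mcw[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  int dx[4]; dims4(x, dx);
  int H = dx[0], W = dx[1], Cin = dx[2], B = dx[3];
  IntegerVector dw = w.attr("dim");
  if (dw.size() != 4 || dw[2] != Cin) stop("weight/input channel mismatch");
  int k = dw[0], Cout = dw[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  NumericVector y((size_t)Ho * Wo * Cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  const mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  mat M(Ho * Wo, k * k * Cin);
  for (int bi = 0; bi < B; ++bi) {
    im2col(x.begin() + (size_t)bi * H * W * Cin, H, W, Cin, k, stride, pad,
           Ho, Wo, M);
    mat Y(y.begin() + (size_t)bi * Ho * Wo * Cout, Ho * Wo, Cout, false, true);
    Y = M * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  int dx[4]; dims4(x, dx);
  int H = dx[0], W = dx[1], Cin = dx[2], B = dx[3];
  IntegerVector dw = w.attr("dim");
  int k = dw[0], Cout = dw[3];
  int dg[4]; dims4(gy, dg);
  int Ho = dg[0], Wo = dg[1];
  const mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  NumericVector gx((size_t)H * W * Cin * B);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  NumericVector gw((size_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector gb(Cout);
  mat GW(gw.begin(), k * k * Cin, Cout, false, true);
  mat M(Ho * Wo, k * k * Cin);
  for (int bi = 0; bi < B; ++bi) {
    const mat Gy(const_cast<double*>(gy.begin()) + (size_t)bi * Ho * Wo * Cout,
                 Ho * Wo, Cout, false, true);
    im2col(x.begin() + (size_t)bi * H * W * Cin, H, W, Cin, k, stride, pad,
           Ho, Wo, M);
    GW += M.t() * Gy;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(Gy.col(co));
    mat GM = Gy * Wm.t();
    col2im_add(GM, H, W, Cin, k, stride, pad, Ho, Wo,
               gx.begin() + (size_t)bi * H * W * Cin);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling with implicit -Inf padding; records the within-slice spatial
// argmax (0-based h + H*w) for the backward pass.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int kh, int kw, int stride, int pad) {
  int dx[4]; dims4(x, dx);
  int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("pooling output would be empty");
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector am((size_t)Ho * Wo * C * B);
  am.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  size_t o = 0;
  for (int sl = 0; sl < C * B; ++sl) {
    const double* xs = x.begin() + (size_t)sl * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = ho * stride - pad;
        double best = -INFINITY; int barg = -1;
        for (int dw2 = 0; dw2 < kw; ++dw2) {
          int wi = w0 + dw2;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int hi = h0 + dh;
            if (hi < 0 || hi >= H) continue;
            double v = xs[hi + (size_t)H * wi];
            if (v > best) { best = v; barg = hi + H * wi; }
          }
        }
        // column-major output: iterate ho fastest within wo
        size_t oi = (size_t)sl * Ho * Wo + (size_t)Ho * wo + ho;
        y[oi] = best; am[oi] = barg;
        ++o;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector am, NumericVector gy,
                              int H, int W) {
  int dg[4]; dims4(gy, dg);
  int Ho = dg[0], Wo = dg[1], C = dg[2], B = dg[3];
  NumericVector gx((size_t)H * W * C * B);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  for (int sl = 0; sl < C * B; ++sl) {
    double* gs = gx.begin() + (size_t)sl * H * W;
    const double* gys = gy.begin() + (size_t)sl * Ho * Wo;
    const int* ams = am.begin() + (size_t)sl * Ho * Wo;
    for (int i = 0; i < Ho * Wo; ++i)
      if (ams[i] >= 0) gs[ams[i]] += gys[i];
  }
  return gx;
}
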