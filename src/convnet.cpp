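// 2-D convolution forward/backward via im2col + GEMM.
// Tensor layout follows R column-major arrays: activations (H, W, C, N),
// weights (K, K, Cin, Cout). Only what the network needs: square kernels,
// symmetric zero padding, uniform stride.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int K, int stride, int pad, int Ho, int Wo,
                   arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        double* dst = col.colptr(kh + K * (kw + K * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int win = wo * stride + kw - pad;
          bool wok = win >= 0 && win < W;
          for (int ho = 0; ho < Ho; ++ho) {
            int hin = ho * stride + kh - pad;
            dst[ho + (size_t)Ho * wo] =
              (wok && hin >= 0 && hin < H) ? xc[hin + (size_t)H * win] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* gx, int H, int W, int C,
                       int K, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* gxc = gx + (size_t)H * W * c;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double* src = col.colptr(kh + K * (kw + K * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int win = wo * stride + kw - pad;
          if (win < 0 || win >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hin = ho * stride + kh - pad;
            if (hin < 0 || hin >= H) continue;
            gxc[hin + (size_t)H * win] += src[ho + (size_t)Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch in conv2d_fwd");
  int Ho = (H + 2 * pad - K) / stride + 1;
  int Wo = (W + 2 * pad - K) / stride + 1;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), (size_t)K * K * C, Cout, false);
  arma::mat col((size_t)Ho * Wo, (size_t)K * K * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, K, stride, pad, Ho, Wo, col);
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n, (size_t)Ho * Wo, Cout,
                false, true);
    Y = col * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((size_t)K * K * C * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat Wm(w.begin(), (size_t)K * K * C, Cout, false);
  arma::mat gWm(gw.begin(), (size_t)K * K * C, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  arma::mat col((size_t)Ho * Wo, (size_t)K * K * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, K, stride, pad, Ho, Wo, col);
    arma::mat Gy(gy.begin() + (size_t)Ho * Wo * Cout * n, (size_t)Ho * Wo, Cout,
                 false);
    gWm += col.t() * Gy;
    gbv += arma::sum(Gy, 0).t();
    arma::mat gcol = Gy * Wm.t();
    col2im_add(gcol, gx.begin() + (size_t)H * W * C * n, H, W, C, K, stride,
               pad, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
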