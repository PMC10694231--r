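// Batched 2-D convolution forward/backward kernels (im2col + GEMM) for the
// compact regression CNN. Layout follows R column-major arrays:
// inputs H x W x C x N, kernels kh x kw x Cin x Cout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather one sample (H x W x C slice) into an im2col matrix of shape
// (Ho*Wo) x (kh*kw*Cin). Out-of-range (padded) taps contribute zero.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int colidx = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = x[hi + H * (wi + W * c)];
            col(ho + Ho * wo, colidx) = v;
          }
        }
      }
    }
  }
}

// Scatter-add an im2col-shaped gradient back onto the input sample.
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int colidx = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            dx[hi + H * (wi + W * c)] += col(ho + Ho * wo, colidx);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_fw(NumericVector x, NumericVector w, NumericVector b,
                      int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv_fw");
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(Ho * Wo, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat out = col * Wm;               // (Ho*Wo) x Cout
    for (int co = 0; co < Cout; ++co) out.col(co) += b[co];
    std::copy(out.begin(), out.end(),
              y.begin() + (size_t)n * Ho * Wo * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List conv_bw(NumericVector x, NumericVector w, NumericVector dy,
             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dWm(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(Ho * Wo, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                  Ho * Wo, Cout, false);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    dWm += col.t() * dyn;
    db += arma::sum(dyn, 0).t();
    arma::mat dcol = dyn * Wm.t();          // (Ho*Wo) x (kh*kw*Cin)
    col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
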