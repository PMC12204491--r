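// Minimal dilated 2D convolution kernels (im2col + GEMM) with exact
// gradients, used by the patch-based dilated U-Net. Layout is R column-major:
// activations (H, W, C, N), weights (k, k, Cin, Cout), "same" zero padding
// with pad = d * (k - 1) / 2 so odd kernels preserve spatial size.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int d) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = d * (k - 1) / 2;
  arma::mat M(H * W, k * k * C, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki, ++col) {
        const int di = ki * d - pad, dj = kj * d - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            M(i + j * H, col) = x(si, sj, c);
          }
        }
      }
  return M;
}

static void col2im_add(arma::cube& gx, const arma::mat& Gm, int k, int d) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  const int pad = d * (k - 1) / 2;
  int col = 0;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki, ++col) {
        const int di = ki * d - pad, dj = kj * d - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            gx(si, sj, c) += Gm(i + j * H, col);
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x_, NumericVector w_,
                           NumericVector b_, int dilation) {
  IntegerVector xd = x_.attr("dim"); // H W Cin N
  IntegerVector wd = w_.attr("dim"); // k k Cin Cout
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch in conv forward");
  arma::mat Wm(w_.begin(), k * k * C, Cout, false);
  arma::rowvec b(b_.begin(), Cout);
  NumericVector y_((R_xlen_t)H * W * Cout * N);
  y_.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::cube xc(x_.begin() + (size_t)n * H * W * C, H, W, C, false, true);
    arma::mat Y = im2col(xc, k, dilation) * Wm;
    Y.each_row() += b;
    std::copy(Y.begin(), Y.end(), y_.begin() + (size_t)n * H * W * Cout);
  }
  return y_;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x_, NumericVector w_, NumericVector gy_,
                  int dilation) {
  IntegerVector xd = x_.attr("dim");
  IntegerVector wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  arma::mat Wm(w_.begin(), k * k * C, Cout, false);
  NumericVector gx_((R_xlen_t)H * W * C * N);
  gx_.attr("dim") = xd;
  arma::mat gW(k * k * C, Cout, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::cube xc(x_.begin() + (size_t)n * H * W * C, H, W, C, false, true);
    arma::mat Gy(gy_.begin() + (size_t)n * H * W * Cout, H * W, Cout, false,
                 true);
    arma::mat M = im2col(xc, k, dilation);
    gW += M.t() * Gy;
    gb += arma::sum(Gy, 0);
    arma::mat Gm = Gy * Wm.t();
    arma::cube gxc(gx_.begin() + (size_t)n * H * W * C, H, W, C, false, true);
    col2im_add(gxc, Gm, k, dilation);
  }
  NumericVector gW_(gW.begin(), gW.end());
  gW_.attr("dim") = wd;
  NumericVector gb_(gb.begin(), gb.end());
  return List::create(_["gx"] = gx_, _["gW"] = gW_, _["gb"] = gb_);
}

// 2x2 max pooling, stride 2; even H and W assumed (checked in R)
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x_) {
  IntegerVector xd = x_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y_((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx_((R_xlen_t)Ho * Wo * C * N); // 0-based linear into x
  y_.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx_.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* x = x_.begin();
  double* y = y_.begin();
  int* idx = idx_.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const size_t xoff = cn * H * W, yoff = cn * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        size_t best = xoff + (size_t)(2 * j) * H + 2 * i;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            size_t p = xoff + (size_t)(2 * j + dj) * H + (2 * i + di);
            if (x[p] > x[best]) best = p;
          }
        y[yoff + (size_t)j * Ho + i] = x[best];
        idx[yoff + (size_t)j * Ho + i] = (int)best;
      }
  }
  return List::create(_["y"] = y_, _["idx"] = idx_);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy_, IntegerVector idx_,
                              IntegerVector xdim) {
  NumericVector gx_((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx_.attr("dim") = xdim;
  double* gx = gx_.begin();
  const double* gy = gy_.begin();
  const int* idx = idx_.begin();
  const R_xlen_t n = gy_.size();
  for (R_xlen_t t = 0; t < n; ++t) gx[idx[t]] += gy[t];
  return gx_;
}
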