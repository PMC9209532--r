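// Minimal 2D convolution kernels for the SRGAN: im2col + GEMM forward,
// and the matching gradients w.r.t. input, weights and bias.
//
// Layout conventions (column-major, matching R arrays):
//   x     : cube (H, W, C_in)          -- one image, channels last
//   w     : mat  (k*k*C_in, C_out)     -- row index = c*k*k + dj*k + di
//   out   : cube (Ho, Wo, C_out)
// Zero padding `pad`, square kernel `k`, equal stride in both directions.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// first output index whose input index d + i*stride - pad is >= 0
static inline int lo_bound(int d, int stride, int pad) {
  const int num = pad - d;
  return num <= 0 ? 0 : (num + stride - 1) / stride;
}
// last output index whose input index stays < n
static inline int hi_bound(int d, int stride, int pad, int n, int n_out) {
  const int m = (n - 1 + pad - d) / stride;
  return m < n_out - 1 ? m : n_out - 1;
}

static mat im2col(const cube& x, int k, int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols((uword)Ho * Wo, (uword)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      const int j0 = lo_bound(dj, stride, pad);
      const int j1 = hi_bound(dj, stride, pad, W, Wo);
      for (int di = 0; di < k; ++di) {
        const uword colIdx = (uword)c * k * k + (uword)dj * k + di;
        double* dst0 = cols.colptr(colIdx);
        const int i0 = lo_bound(di, stride, pad);
        const int i1 = hi_bound(di, stride, pad, H, Ho);
        for (int j = j0; j <= j1; ++j) {
          const int jin = j * stride - pad + dj;
          const double* src = x.slice_colptr(c, jin) + di - pad;
          double* dst = dst0 + (uword)Ho * j;
          if (stride == 1) {
            for (int i = i0; i <= i1; ++i) dst[i] = src[i];
          } else {
            for (int i = i0; i <= i1; ++i) dst[i] = src[(long)i * stride];
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add adjoint of im2col
static cube col2im(const mat& cols, int H, int W, int C, int k, int stride,
                   int pad, int Ho, int Wo) {
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      const int j0 = lo_bound(dj, stride, pad);
      const int j1 = hi_bound(dj, stride, pad, W, Wo);
      for (int di = 0; di < k; ++di) {
        const uword colIdx = (uword)c * k * k + (uword)dj * k + di;
        const double* src0 = cols.colptr(colIdx);
        const int i0 = lo_bound(di, stride, pad);
        const int i1 = hi_bound(di, stride, pad, H, Ho);
        for (int j = j0; j <= j1; ++j) {
          const int jin = j * stride - pad + dj;
          double* dst = x.slice_colptr(c, jin) + di - pad;
          const double* src = src0 + (uword)Ho * j;
          if (stride == 1) {
            for (int i = i0; i <= i1; ++i) dst[i] += src[i];
          } else {
            for (int i = i0; i <= i1; ++i) dst[(long)i * stride] += src[i];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube nn_conv_fw(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int stride, int pad) {
  const int k = (int)std::lround(std::sqrt((double)(w.n_rows / x.n_slices)));
  if ((uword)k * k * x.n_slices != w.n_rows)
    Rcpp::stop("weight rows do not match kernel^2 * input channels");
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  if (Ho < 1 || Wo < 1) Rcpp::stop("kernel larger than padded input");
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat o = cols * w;                       // (Ho*Wo, C_out)
  o.each_row() += b.t();
  cube out(Ho, Wo, w.n_cols);
  for (uword c = 0; c < w.n_cols; ++c)
    out.slice(c) = reshape(o.col(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bw(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gout, int stride, int pad) {
  const int k = (int)std::lround(std::sqrt((double)(w.n_rows / x.n_slices)));
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  mat G((uword)Ho * Wo, gout.n_slices);
  for (uword c = 0; c < gout.n_slices; ++c)
    G.col(c) = vectorise(gout.slice(c));
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat gw = cols.t() * G;
  vec gb = sum(G, 0).t();
  mat gcols = G * w.t();
  cube gx = col2im(gcols, x.n_rows, x.n_cols, x.n_slices, k, stride, pad,
                   Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
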