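// Convolution im2col/col2im kernels for the network blocks.
// Tensor layout matches the R arrays: (H, W, C, N), column-major, so element
// (h, w, c, n) sits at h + H*(w + W*(c + C*n)). The unfolded matrix has
// k*k*C rows (row = c*k*k + kc*k + kr, kernel row offset fastest) and
// Ho*Wo*N columns (col = n*Ho*Wo + wo*Ho + ho, output row fastest).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims,
                         int k, int stride, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int k2 = k * k;
  NumericMatrix cols(k2 * C, Ho * Wo * N);
  double *out = cols.begin();
  const double *in = x.begin();
  const R_xlen_t nrow = (R_xlen_t)k2 * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t colidx = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        double *dst = out + colidx * nrow;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *plane = in + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
          for (int kc = 0; kc < k; ++kc) {
            const int w = w0 + kc;
            for (int kr = 0; kr < k; ++kr) {
              const int h = h0 + kr;
              dst[c * k2 + kc * k + kr] =
                (h >= 0 && h < H && w >= 0 && w < W)
                  ? plane[(R_xlen_t)w * H + h] : 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, IntegerVector dims,
                         int k, int stride, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int k2 = k * k;
  NumericVector x((R_xlen_t)H * W * C * N);
  double *out = x.begin();
  const double *in = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)k2 * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t colidx = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        const double *src = in + colidx * nrow;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double *plane = out + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
          for (int kc = 0; kc < k; ++kc) {
            const int w = w0 + kc;
            if (w < 0 || w >= W) continue;
            for (int kr = 0; kr < k; ++kr) {
              const int h = h0 + kr;
              if (h >= 0 && h < H)
                plane[(R_xlen_t)w * H + h] += src[c * k2 + kc * k + kr];
            }
          }
        }
      }
    }
  }
  return x;
}
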