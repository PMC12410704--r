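#include <Rcpp.h>
using namespace Rcpp;

// 3x3 same-padding im2col for a (H, W, C, N) column-major image stack.
// Output rows are ordered h fastest, then w, then n; columns are ordered
// (ky, kx) fastest, then channel, matching conv_col2im below.

// [[Rcpp::export]]
NumericMatrix conv_im2col(NumericVector x, int H, int W, int C, int N) {
  const int k = 3, pad = 1;
  NumericMatrix out((R_xlen_t)H * W * N, k * k * C);
  const double* xp = REAL(x);
  double* op = REAL(out);
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const R_xlen_t col = ky + k * kx + (R_xlen_t)k * k * c;
        double* ocol = op + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + ((R_xlen_t)n * C + c) * H * W;
          for (int w = 0; w < W; ++w) {
            const int xw = w + kx - pad;
            double* od = ocol + (R_xlen_t)H * (w + (R_xlen_t)W * n);
            if (xw < 0 || xw >= W) {
              for (int h = 0; h < H; ++h) od[h] = 0.0;
            } else {
              const double* xcol = xc + (R_xlen_t)H * xw;
              for (int h = 0; h < H; ++h) {
                const int xh = h + ky - pad;
                od[h] = (xh >= 0 && xh < H) ? xcol[xh] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of conv_im2col: scatter-add matrix gradients back to image space.

// [[Rcpp::export]]
NumericVector conv_col2im(NumericMatrix m, int H, int W, int C, int N) {
  const int k = 3, pad = 1;
  NumericVector out((R_xlen_t)H * W * C * N);
  double* op = REAL(out);
  const double* mp = REAL(m);
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const R_xlen_t col = ky + k * kx + (R_xlen_t)k * k * c;
        const double* mcol = mp + col * nrow;
        for (int n = 0; n < N; ++n) {
          double* oc = op + ((R_xlen_t)n * C + c) * H * W;
          for (int w = 0; w < W; ++w) {
            const int xw = w + kx - pad;
            if (xw < 0 || xw >= W) continue;
            const double* md = mcol + (R_xlen_t)H * (w + (R_xlen_t)W * n);
            double* ocol = oc + (R_xlen_t)H * xw;
            for (int h = 0; h < H; ++h) {
              const int xh = h + ky - pad;
              if (xh >= 0 && xh < H) ocol[xh] += md[h];
            }
          }
        }
      }
    }
  }
  return out;
}
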