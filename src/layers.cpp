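// Hot paths of the 1D convolution layers: patch extraction (im2col) and its
// adjoint scatter-add (col2im). Arrays are laid out (N, L, C) column-major,
// matching the R batch representation; patch matrices are (N*Lo, k*C) with
// column index c + t*C for tap t and input channel c.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_nlc(NumericVector X, int k) {
  IntegerVector d = X.attr("dim");
  const int N = d[0], L = d[1], C = d[2];
  const int Lo = L - k + 1;
  NumericMatrix out((R_xlen_t)N * Lo, (R_xlen_t)k * C);
  const double *px = X.begin();
  double *po = out.begin();
  for (int t = 0; t < k; ++t) {
    for (int c = 0; c < C; ++c) {
      double *col = po + (R_xlen_t)(t * C + c) * N * Lo;
      for (int pos = 0; pos < Lo; ++pos) {
        const double *src = px + (R_xlen_t)(pos + t) * N + (R_xlen_t)c * N * L;
        std::copy(src, src + N, col + (R_xlen_t)pos * N);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_nlc(NumericMatrix dP, int N, int L, int C, int k) {
  const int Lo = L - k + 1;
  NumericVector out((R_xlen_t)N * L * C);
  out.attr("dim") = IntegerVector::create(N, L, C);
  double *po = out.begin();
  const double *pp = dP.begin();
  for (int t = 0; t < k; ++t) {
    for (int c = 0; c < C; ++c) {
      const double *col = pp + (R_xlen_t)(t * C + c) * N * Lo;
      for (int pos = 0; pos < Lo; ++pos) {
        double *dst = po + (R_xlen_t)(pos + t) * N + (R_xlen_t)c * N * L;
        const double *src = col + (R_xlen_t)pos * N;
        for (int n = 0; n < N; ++n) dst[n] += src[n];
      }
    }
  }
  return out;
}
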