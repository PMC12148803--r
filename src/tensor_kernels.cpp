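// Data-movement kernels behind the convolution layers. The arithmetic-heavy
// matrix products stay in R (BLAS via crossprod/%*%); these kernels only do
// the gathers, scatters and layout changes that are slow as R vector ops.

#include <Rcpp.h>
using namespace Rcpp;

// Gather x[idx] (1-based indices) into a nrow x (len/nrow) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_gather(const NumericVector& x, const IntegerVector& idx,
                         const int nrow) {
  const R_xlen_t n = idx.size();
  NumericMatrix out(no_init(nrow, n / nrow));
  double* po = REAL(out);
  const double* px = REAL(x);
  const int* pi = INTEGER(idx);
  for (R_xlen_t t = 0; t < n; ++t) po[t] = px[pi[t] - 1];
  return out;
}

// out[idx] += vals over a fresh zero vector of length out_len.
// [[Rcpp::export]]
NumericVector cpp_scatter_add(const IntegerVector& idx,
                              const NumericVector& vals,
                              const double out_len) {
  NumericVector out((R_xlen_t) out_len);
  double* po = REAL(out);
  const double* pv = REAL(vals);
  const int* pi = INTEGER(idx);
  const R_xlen_t n = idx.size();
  for (R_xlen_t t = 0; t < n; ++t) po[pi[t] - 1] += pv[t];
  return out;
}

// (H, W, C, N) array -> (C x (H*W*N)) matrix, channel-first columns ordered
// by (spatial position, sample).
// [[Rcpp::export]]
NumericMatrix cpp_chfirst(const NumericVector& x, const int HW, const int C,
                          const int N) {
  NumericMatrix out(no_init(C, (R_xlen_t) HW * N));
  double* po = REAL(out);
  const double* px = REAL(x);
  for (int n = 0; n < N; ++n) {
    const R_xlen_t xoff = (R_xlen_t) HW * C * n;
    const R_xlen_t ooff = (R_xlen_t) C * HW * n;
    for (int c = 0; c < C; ++c)
      for (int e = 0; e < HW; ++e)
        po[ooff + (R_xlen_t) e * C + c] = px[xoff + (R_xlen_t) c * HW + e];
  }
  return out;
}

// Inverse of cpp_chfirst: (C x (H*W*N)) matrix -> (H, W, C, N) vector
// (dim attribute set by the caller).
// [[Rcpp::export]]
NumericVector cpp_chlast(const NumericMatrix& y, const int HW, const int C,
                         const int N) {
  NumericVector out(no_init((R_xlen_t) HW * C * N));
  double* po = REAL(out);
  const double* py = REAL(y);
  for (int n = 0; n < N; ++n) {
    const R_xlen_t ooff = (R_xlen_t) HW * C * n;
    const R_xlen_t yoff = (R_xlen_t) C * HW * n;
    for (int e = 0; e < HW; ++e)
      for (int c = 0; c < C; ++c)
        po[ooff + (R_xlen_t) c * HW + e] = py[yoff + (R_xlen_t) e * C + c];
  }
  return out;
}

// Zero-pad an (H, W, C, N) array by p on both spatial axes.
// [[Rcpp::export]]
NumericVector cpp_pad4(const NumericVector& x, const int H, const int W,
                       const int C, const int N, const int p) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  NumericVector out((R_xlen_t) Hp * Wp * C * N);
  double* po = REAL(out);
  const double* px = REAL(x);
  for (R_xlen_t cn = 0; cn < (R_xlen_t) C * N; ++cn) {
    const double* src = px + cn * H * W;
    double* dst = po + cn * Hp * Wp;
    for (int j = 0; j < W; ++j)
      std::copy(src + (R_xlen_t) j * H, src + (R_xlen_t) (j + 1) * H,
                dst + (R_xlen_t) (j + p) * Hp + p);
  }
  return out;
}

// Crop the padding back off: adjoint of cpp_pad4.
// [[Rcpp::export]]
NumericVector cpp_unpad4(const NumericVector& x, const int H, const int W,
                         const int C, const int N, const int p) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  NumericVector out(no_init((R_xlen_t) H * W * C * N));
  double* po = REAL(out);
  const double* px = REAL(x);
  for (R_xlen_t cn = 0; cn < (R_xlen_t) C * N; ++cn) {
    const double* src = px + cn * Hp * Wp;
    double* dst = po + cn * H * W;
    for (int j = 0; j < W; ++j)
      std::copy(src + (R_xlen_t) (j + p) * Hp + p,
                src + (R_xlen_t) (j + p) * Hp + p + H,
                dst + (R_xlen_t) j * H);
  }
  return out;
}

// Leaky-ReLU forward and its input-gradient, fused.
// [[Rcpp::export]]
NumericVector cpp_lrelu(const NumericVector& x, const double slope) {
  NumericVector out(clone(x));
  double* po = REAL(out);
  const R_xlen_t n = out.size();
  for (R_xlen_t t = 0; t < n; ++t)
    if (po[t] < 0) po[t] *= slope;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_grad(const NumericVector& x, const NumericVector& dy,
                             const double slope) {
  NumericVector out(no_init(x.size()));
  double* po = REAL(out);
  const double* px = REAL(x);
  const double* pd = REAL(dy);
  const R_xlen_t n = out.size();
  for (R_xlen_t t = 0; t < n; ++t)
    po[t] = px[t] > 0 ? pd[t] : slope * pd[t];
  return out;
}
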