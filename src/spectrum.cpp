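#include <Rcpp.h>
using namespace Rcpp;

// Assemble a Hermitian white Gaussian spectrum (per column) scaled by the
// real amplitude envelope `amp` (n x ne). re/im are half x ne standard
// normal draws; dc is length ne. The result, inverse-FFTed and divided by
// n, is a real Gaussian series whose per-bin variance follows amp^2 / n.
// [[Rcpp::export]]
ComplexMatrix hermitian_spectrum_cpp(NumericMatrix re, NumericMatrix im,
                                     NumericVector dc, NumericMatrix amp) {
  const int half = re.nrow(), ne = re.ncol();
  const int n = amp.nrow();
  const bool even = (n % 2 == 0);
  const double sq = std::sqrt(n / 2.0), sqn = std::sqrt((double)n);
  ComplexMatrix z(n, ne);
  for (int j = 0; j < ne; ++j) {
    const double *aj = &amp(0, j);
    Rcomplex *zj = &z(0, j);
    zj[0].r = dc[j] * sqn * aj[0];
    zj[0].i = 0.0;
    const int top = even ? half - 1 : half;
    for (int k = 0; k < top; ++k) {
      const double a = aj[k + 1] * sq;
      const double zr = re(k, j) * a, zi = im(k, j) * a;
      zj[k + 1].r = zr;          zj[k + 1].i = zi;
      zj[n - 1 - k].r = zr;      zj[n - 1 - k].i = -zi;
    }
    if (even) {
      zj[half].r = re(half - 1, j) * sqn * aj[half];
      zj[half].i = 0.0;
    }
  }
  return z;
}

// Squared spectral magnitudes, avoiding R's hypot-based Mod().
// [[Rcpp::export]]
NumericMatrix abs2_cpp(ComplexMatrix z) {
  const int nr = z.nrow(), nc = z.ncol();
  NumericMatrix out(nr, nc);
  const Rcomplex *p = COMPLEX(z);
  double *o = REAL(out);
  const R_xlen_t n = (R_xlen_t)nr * nc;
  for (R_xlen_t i = 0; i < n; ++i) o[i] = p[i].r * p[i].r + p[i].i * p[i].i;
  return out;
}
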