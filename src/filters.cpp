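#include <Rcpp.h>
using namespace Rcpp;

static inline void df2t_pass(const double *bb, const double *aa, int nz,
                             const double *x, double *y, R_xlen_t n) {
  if (nz == 8) {  // 4th-order band-pass, the common case: fully unrolled
    double z0 = 0, z1 = 0, z2 = 0, z3 = 0, z4 = 0, z5 = 0, z6 = 0, z7 = 0;
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4],
                 b5 = bb[5], b6 = bb[6], b7 = bb[7], b8 = bb[8];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4],
                 a5 = aa[5], a6 = aa[6], a7 = aa[7], a8 = aa[8];
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi + z2 - a2 * yi;
      z2 = b3 * xi + z3 - a3 * yi;
      z3 = b4 * xi + z4 - a4 * yi;
      z4 = b5 * xi + z5 - a5 * yi;
      z5 = b6 * xi + z6 - a6 * yi;
      z6 = b7 * xi + z7 - a7 * yi;
      z7 = b8 * xi - a8 * yi;
      y[i] = yi;
    }
    return;
  }
  double z[32];
  for (int j = 0; j < nz; ++j) z[j] = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j) z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
}

// Zero-phase (forward-reverse) IIR filtering with odd extension of `pad`
// samples at both ends; output has the length of x.
// [[Rcpp::export]]
NumericVector filtfilt_cpp(NumericVector b, NumericVector a, NumericVector x,
                           int pad) {
  const int nb = b.size(), na = a.size();
  const int nz = std::max(na, nb) - 1;
  if (nz >= 32) stop("filter order too large");
  double bb[32] = {0.0}, aa[32] = {0.0};
  const double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  const R_xlen_t n = x.size();
  if (pad > n - 1) pad = (int)(n - 1);
  const R_xlen_t ne = n + 2 * pad;
  std::vector<double> xe(ne), ye(ne);
  const double *xp = REAL(x);
  for (int i = 0; i < pad; ++i) xe[i] = 2.0 * xp[0] - xp[pad - i];
  std::copy(xp, xp + n, xe.begin() + pad);
  for (int i = 0; i < pad; ++i) xe[pad + n + i] = 2.0 * xp[n - 1] - xp[n - 2 - i];
  df2t_pass(bb, aa, nz, xe.data(), ye.data(), ne);
  std::reverse(ye.begin(), ye.end());
  df2t_pass(bb, aa, nz, ye.data(), xe.data(), ne);  // reuse xe as scratch
  NumericVector out(n);
  // second pass ran on reversed data; un-reverse while trimming the pads
  for (R_xlen_t i = 0; i < n; ++i) out[i] = xe[ne - 1 - (pad + i)];
  return out;
}

// Direct-form II transposed IIR filter with zero initial conditions.
// b, a are the numerator/denominator coefficients (a[0] need not be 1).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(na, nb) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j) z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
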