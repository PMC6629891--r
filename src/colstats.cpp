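#include <Rcpp.h>
using namespace Rcpp;

// Per-column sd, range, and range of the first difference, in one pass.
// [[Rcpp::export]]
List col_quality_stats_cpp(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector sd(nc), rng(nc), d1rng(nc);
  for (int j = 0; j < nc; ++j) {
    const double *x = &m(0, j);
    double s = 0.0, s2 = 0.0;
    double mn = x[0], mx = x[0];
    double dmn = R_PosInf, dmx = R_NegInf;
    for (int i = 0; i < nr; ++i) {
      const double v = x[i];
      s += v; s2 += v * v;
      if (v < mn) mn = v;
      if (v > mx) mx = v;
      if (i > 0) {
        const double d = v - x[i - 1];
        if (d < dmn) dmn = d;
        if (d > dmx) dmx = d;
      }
    }
    const double mean = s / nr;
    double varr = (s2 - nr * mean * mean) / (nr - 1);
    if (varr < 0) varr = 0;
    sd[j] = std::sqrt(varr);
    rng[j] = mx - mn;
    d1rng[j] = (nr > 1) ? (dmx - dmn) : 0.0;
  }
  return List::create(_["sd"] = sd, _["range"] = rng, _["d1_range"] = d1rng);
}
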