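#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for Latent Dirichlet Allocation.
//
// Tokens are passed as two parallel 0-based integer vectors (document id,
// word id). Uses R's RNG, so results are reproducible through set.seed()
// in the calling R code. After burn-in, phi and theta are posterior means
// over the retained sweeps of the smoothed count estimators.
// [[Rcpp::export]]
List lda_gibbs_train_cpp(IntegerVector doc, IntegerVector wrd,
                         int D, int V, int K,
                         double alpha, double eta,
                         int n_burnin, int n_samples) {
  const R_xlen_t N = doc.size();
  const double Veta = V * eta;
  std::vector<int> z(N);
  std::vector<double> ndk((size_t)D * K, 0.0), nkw((size_t)K * V, 0.0);
  std::vector<double> nk(K, 0.0), nd(D, 0.0);

  RNGScope scope;
  for (R_xlen_t i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk[(size_t)doc[i] * K + k] += 1.0;
    nkw[(size_t)k * V + wrd[i]] += 1.0;
    nk[k] += 1.0;
    nd[doc[i]] += 1.0;
  }

  const int n_iter = n_burnin + n_samples;
  NumericVector loglik(n_iter);
  std::vector<double> phisum((size_t)K * V, 0.0), thetasum((size_t)D * K, 0.0);
  std::vector<double> p(K), inv_nk(K);

  for (int it = 0; it < n_iter; ++it) {
    for (int k = 0; k < K; ++k) inv_nk[k] = 1.0 / (nk[k] + Veta);
    for (R_xlen_t i = 0; i < N; ++i) {
      const int d = doc[i], w = wrd[i];
      int k = z[i];
      double *drow = &ndk[(size_t)d * K];
      drow[k] -= 1.0;
      nkw[(size_t)k * V + w] -= 1.0;
      nk[k] -= 1.0;
      inv_nk[k] = 1.0 / (nk[k] + Veta);
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        tot += (drow[kk] + alpha) * (nkw[(size_t)kk * V + w] + eta) * inv_nk[kk];
        p[kk] = tot;
      }
      const double u = unif_rand() * tot;
      int knew = 0;
      while (knew < K - 1 && p[knew] < u) ++knew;
      z[i] = knew;
      drow[knew] += 1.0;
      nkw[(size_t)knew * V + w] += 1.0;
      nk[knew] += 1.0;
      inv_nk[knew] = 1.0 / (nk[knew] + Veta);
    }

    // Joint log p(w, z | alpha, eta) up to an additive constant.
    double ll = 0.0;
    for (int k = 0; k < K; ++k) {
      const double *row = &nkw[(size_t)k * V];
      for (int w = 0; w < V; ++w) ll += ::Rf_lgammafn(row[w] + eta);
      ll -= ::Rf_lgammafn(nk[k] + Veta);
    }
    for (int d = 0; d < D; ++d) {
      const double *row = &ndk[(size_t)d * K];
      for (int k = 0; k < K; ++k) ll += ::Rf_lgammafn(row[k] + alpha);
      ll -= ::Rf_lgammafn(nd[d] + K * alpha);
    }
    loglik[it] = ll;

    if (it >= n_burnin) {
      for (int k = 0; k < K; ++k) {
        const double denom = nk[k] + Veta;
        double *ps = &phisum[(size_t)k * V];
        const double *row = &nkw[(size_t)k * V];
        for (int w = 0; w < V; ++w) ps[w] += (row[w] + eta) / denom;
      }
      for (int d = 0; d < D; ++d) {
        const double denom = nd[d] + K * alpha;
        double *ts = &thetasum[(size_t)d * K];
        const double *row = &ndk[(size_t)d * K];
        for (int k = 0; k < K; ++k) ts[k] += (row[k] + alpha) / denom;
      }
    }
  }

  NumericMatrix phi(K, V), theta(D, K);
  const double ns = (n_samples > 0) ? (double)n_samples : 1.0;
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w) phi(k, w) = phisum[(size_t)k * V + w] / ns;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta(d, k) = thetasum[(size_t)d * K + k] / ns;

  return List::create(_["phi"] = phi, _["theta"] = theta, _["loglik"] = loglik);
}

// Fold-in inference: Gibbs sampling of token-topic assignments for new
// documents with the topic-word distributions phi (K x V) held fixed.
// Documents are conditionally independent given phi, so any number of
// documents can be processed in one call.
// [[Rcpp::export]]
NumericMatrix lda_gibbs_infer_cpp(IntegerVector doc, IntegerVector wrd, int D,
                                  NumericMatrix phi, double alpha,
                                  int n_burnin, int n_samples) {
  const R_xlen_t N = doc.size();
  const int K = phi.nrow();
  std::vector<int> z(N);
  std::vector<double> ndk((size_t)D * K, 0.0), nd(D, 0.0);

  RNGScope scope;
  for (R_xlen_t i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk[(size_t)doc[i] * K + k] += 1.0;
    nd[doc[i]] += 1.0;
  }

  const int n_iter = n_burnin + n_samples;
  std::vector<double> thetasum((size_t)D * K, 0.0);
  std::vector<double> p(K);
  // phi is column-major with K rows: phi[w * K + k] walks topics contiguously
  const double *ph = REAL(phi);

  for (int it = 0; it < n_iter; ++it) {
    for (R_xlen_t i = 0; i < N; ++i) {
      const int d = doc[i], w = wrd[i];
      int k = z[i];
      ndk[(size_t)d * K + k] -= 1.0;
      double tot = 0.0;
      const double *pw = &ph[(size_t)w * K];
      double *nrow = &ndk[(size_t)d * K];
      for (int kk = 0; kk < K; ++kk) {
        tot += (nrow[kk] + alpha) * pw[kk];
        p[kk] = tot;
      }
      const double u = unif_rand() * tot;
      int knew = 0;
      while (knew < K - 1 && p[knew] < u) ++knew;
      z[i] = knew;
      nrow[knew] += 1.0;
    }
    if (it >= n_burnin) {
      for (int d = 0; d < D; ++d) {
        const double denom = nd[d] + K * alpha;
        double *ts = &thetasum[(size_t)d * K];
        const double *row = &ndk[(size_t)d * K];
        for (int k = 0; k < K; ++k) ts[k] += (row[k] + alpha) / denom;
      }
    }
  }

  NumericMatrix theta(D, K);
  const double ns = (n_samples > 0) ? (double)n_samples : 1.0;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta(d, k) = thetasum[(size_t)d * K + k] / ns;
  return theta;
}
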