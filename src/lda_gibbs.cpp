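#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation with symmetric
// Dirichlet priors. Tokens arrive as parallel 0-based doc/word vectors; one
// "pass" is a full sweep over all tokens. Uses R's RNG so results are
// reproducible from set.seed() on the R side.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word,
                   int D, int V, int K, int passes,
                   double alpha, double beta) {
  const int N = doc.size();
  IntegerVector z(N);
  IntegerMatrix nd(D, K);
  IntegerMatrix nw(K, V);
  IntegerVector nk(K);
  IntegerVector ndoc(D);

  // random initialization
  for (int t = 0; t < N; ++t) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[t] = k;
    nd(doc[t], k)++;
    nw(k, word[t])++;
    nk[k]++;
    ndoc[doc[t]]++;
  }

  std::vector<double> p(K);
  const double Vbeta = V * beta;
  for (int pass = 0; pass < passes; ++pass) {
    for (int t = 0; t < N; ++t) {
      const int d = doc[t], w = word[t];
      int k = z[t];
      nd(d, k)--; nw(k, w)--; nk[k]--;
      double total = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        p[kk] = (nw(kk, w) + beta) / (nk[kk] + Vbeta) * (nd(d, kk) + alpha);
        total += p[kk];
      }
      double u = unif_rand() * total;
      double cum = 0.0;
      k = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        cum += p[kk];
        if (u <= cum) { k = kk; break; }
      }
      z[t] = k;
      nd(d, k)++; nw(k, w)++; nk[k]++;
    }
  }

  NumericMatrix phi(K, V);
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w)
      phi(k, w) = (nw(k, w) + beta) / (nk[k] + Vbeta);
  NumericMatrix theta(D, K);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k)
      theta(d, k) = (nd(d, k) + alpha) / (ndoc[d] + K * alpha);

  return List::create(_["phi"] = phi, _["theta"] = theta, _["z"] = z + 1);
}
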