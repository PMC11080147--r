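#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation over segment
// bin-count documents. doc/word are 0-based token vectors; returns the
// final topic assignments and count matrices. Uses R's RNG (seed from R).
// [[Rcpp::export]]
List lda_gibbs(IntegerVector doc, IntegerVector word, int K, int V,
               double alpha, double beta, int sweeps) {
  int N = doc.size();
  int D = 0;
  for (int i = 0; i < N; ++i) if (doc[i] + 1 > D) D = doc[i] + 1;

  IntegerVector z(N);
  IntegerMatrix ndk(D, K), nkw(K, V);
  IntegerVector nk(K);

  for (int i = 0; i < N; ++i) {
    int t = (int)(unif_rand() * K);
    if (t >= K) t = K - 1;
    z[i] = t;
    ndk(doc[i], t)++;
    nkw(t, word[i])++;
    nk[t]++;
  }

  std::vector<double> p(K);
  double Vbeta = V * beta;
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < N; ++i) {
      int d = doc[i], w = word[i], t = z[i];
      ndk(d, t)--; nkw(t, w)--; nk[t]--;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (ndk(d, k) + alpha) * (nkw(k, w) + beta) / (nk[k] + Vbeta);
        tot += p[k];
      }
      double u = unif_rand() * tot;
      int k = 0;
      double acc = p[0];
      while (u > acc && k < K - 1) acc += p[++k];
      z[i] = k;
      ndk(d, k)++; nkw(k, w)++; nk[k]++;
    }
  }
  return List::create(_["z"] = z, _["ndk"] = ndk, _["nkw"] = nkw,
                      _["nk"] = nk);
}
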