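#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// docs: list of integer vectors, 0-based word ids into a vocabulary of
//       size V. K topics, symmetric Dirichlet priors alpha (doc-topic)
//       and eta (topic-word). Runs n_iter full sweeps; the returned
//       phi/theta are posterior-mean estimates averaged over the last
//       `n_avg` sweeps (after the preceding sweeps as burn-in), which
//       stabilizes the point estimate without label switching because
//       averaging happens within one chain.
//
// A private mt19937 stream keyed by `seed` makes results independent
// of R's global RNG state and reproducible across platforms.
// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int V, int K, double alpha, double eta,
                   int n_iter, int n_avg, int seed) {
  const int D = docs.size();
  std::vector<std::vector<int>> w(D);
  long total_tokens = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    total_tokens += dv.size();
  }
  if (n_avg < 1) n_avg = 1;
  if (n_avg > n_iter) n_avg = n_iter;

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // count tables
  std::vector<std::vector<int>> ndk(D, std::vector<int>(K, 0));
  std::vector<std::vector<int>> nkw(K, std::vector<int>(V, 0));
  std::vector<int> nk(K, 0);
  std::vector<std::vector<int>> z(D);

  // random initial assignment
  for (int d = 0; d < D; ++d) {
    const int nd = w[d].size();
    z[d].resize(nd);
    for (int i = 0; i < nd; ++i) {
      int k = static_cast<int>(unif(rng) * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      ndk[d][k] += 1;
      nkw[k][w[d][i]] += 1;
      nk[k] += 1;
    }
  }

  NumericMatrix phi_acc(K, V);
  NumericMatrix theta_acc(D, K);
  std::vector<double> p(K);
  const double Veta = V * eta;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      const int nd = w[d].size();
      for (int i = 0; i < nd; ++i) {
        const int word = w[d][i];
        const int old_k = z[d][i];
        ndk[d][old_k] -= 1;
        nkw[old_k][word] -= 1;
        nk[old_k] -= 1;

        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          total += (ndk[d][k] + alpha) * (nkw[k][word] + eta) / (nk[k] + Veta);
          p[k] = total;
        }
        const double u = unif(rng) * total;
        int new_k = 0;
        while (new_k < K - 1 && p[new_k] < u) ++new_k;

        z[d][i] = new_k;
        ndk[d][new_k] += 1;
        nkw[new_k][word] += 1;
        nk[new_k] += 1;
      }
    }
    if (iter >= n_iter - n_avg) {
      for (int k = 0; k < K; ++k) {
        const double denom = nk[k] + Veta;
        for (int v = 0; v < V; ++v) {
          phi_acc(k, v) += (nkw[k][v] + eta) / denom;
        }
      }
      for (int d = 0; d < D; ++d) {
        const double denom = w[d].size() + K * alpha;
        for (int k = 0; k < K; ++k) {
          theta_acc(d, k) += (ndk[d][k] + alpha) / denom;
        }
      }
    }
  }

  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) phi_acc(k, v) /= n_avg;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta_acc(d, k) /= n_avg;

  return List::create(
    _["phi"] = phi_acc,
    _["theta"] = theta_acc,
    _["total_tokens"] = static_cast<double>(total_tokens)
  );
}
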