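#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA with symmetric Dirichlet priors.
// doc/word are 0-based flattened token streams. The RNG is an internal
// mt19937 consuming raw 32-bit draws, so a given seed reproduces the fit
// bit-for-bit on any platform independently of R's RNG state.
// [[Rcpp::export]]
List lda_gibbs(IntegerVector doc, IntegerVector word,
               int n_docs, int n_vocab, int k,
               double alpha, double eta, int n_iter, int seed) {
  const int N = doc.size();
  if (k < 2) stop("k must be >= 2");
  std::mt19937 rng(static_cast<uint32_t>(seed));
  auto runif01 = [&rng]() {
    return (static_cast<double>(rng()) + 0.5) * (1.0 / 4294967296.0);
  };

  std::vector<int> z(N);
  std::vector<int> ndk(static_cast<size_t>(n_docs) * k, 0);
  std::vector<int> nkw(static_cast<size_t>(k) * n_vocab, 0);
  std::vector<int> nk(k, 0);

  for (int i = 0; i < N; ++i) {
    int t = static_cast<int>(runif01() * k);
    if (t >= k) t = k - 1;
    z[i] = t;
    ndk[static_cast<size_t>(doc[i]) * k + t]++;
    nkw[static_cast<size_t>(t) * n_vocab + word[i]]++;
    nk[t]++;
  }

  std::vector<double> p(k);
  const double etaV = eta * n_vocab;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int t = z[i];
      ndk[static_cast<size_t>(d) * k + t]--;
      nkw[static_cast<size_t>(t) * n_vocab + w]--;
      nk[t]--;
      double tot = 0.0;
      for (int j = 0; j < k; ++j) {
        p[j] = (ndk[static_cast<size_t>(d) * k + j] + alpha) *
               (nkw[static_cast<size_t>(j) * n_vocab + w] + eta) /
               (nk[j] + etaV);
        tot += p[j];
      }
      double u = runif01() * tot, cum = 0.0;
      t = k - 1;
      for (int j = 0; j < k; ++j) {
        cum += p[j];
        if (u < cum) { t = j; break; }
      }
      z[i] = t;
      ndk[static_cast<size_t>(d) * k + t]++;
      nkw[static_cast<size_t>(t) * n_vocab + w]++;
      nk[t]++;
    }
  }

  NumericMatrix topic_word(k, n_vocab), doc_topic(n_docs, k);
  for (int t = 0; t < k; ++t) {
    const double denom = nk[t] + etaV;
    for (int w = 0; w < n_vocab; ++w) {
      topic_word(t, w) = (nkw[static_cast<size_t>(t) * n_vocab + w] + eta) / denom;
    }
  }
  for (int d = 0; d < n_docs; ++d) {
    double len = 0.0;
    for (int t = 0; t < k; ++t) len += ndk[static_cast<size_t>(d) * k + t];
    const double denom = len + alpha * k;
    for (int t = 0; t < k; ++t) {
      doc_topic(d, t) = (ndk[static_cast<size_t>(d) * k + t] + alpha) / denom;
    }
  }
  return List::create(_["topic_word"] = topic_word,
                      _["doc_topic"] = doc_topic);
}
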