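#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

// Skip-gram with negative sampling over integer-encoded sentences.
// Single-threaded SGD with a private xorshift RNG so results are exactly
// reproducible for a given seed, independent of R's RNG state.

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".sg_train")]]
Rcpp::NumericMatrix sg_train(Rcpp::List sentences, int vocab_size, int dim,
                             int window, int epochs, int negative,
                             double alpha, Rcpp::NumericVector unigram,
                             int seed) {
  const int V = vocab_size, D = dim;
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // input (syn0) and output (syn1neg) layers, small symmetric init
  std::vector<double> syn0(static_cast<size_t>(V) * D);
  std::vector<double> syn1(static_cast<size_t>(V) * D, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / D;

  // cumulative table for negative sampling from the unigram^0.75 law
  std::vector<double> cum(V);
  double tot = 0.0;
  for (int v = 0; v < V; ++v) { tot += unigram[v]; cum[v] = tot; }

  // pre-decode sentences
  std::vector< std::vector<int> > sents;
  sents.reserve(sentences.size());
  long long total_words = 0;
  for (int i = 0; i < sentences.size(); ++i) {
    Rcpp::IntegerVector s = sentences[i];
    sents.push_back(std::vector<int>(s.begin(), s.end()));
    total_words += s.size();
  }

  std::vector<double> grad(D);
  const long long train_total = total_words * (long long)epochs;
  long long seen = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t si = 0; si < sents.size(); ++si) {
      const std::vector<int>& sent = sents[si];
      const int n = (int)sent.size();
      for (int pos = 0; pos < n; ++pos) {
        ++seen;
        double lr = alpha * (1.0 - (double)seen / (train_total + 1));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        const int center = sent[pos] - 1; // R is 1-based
        // dynamic window as in word2vec: effective radius in [1, window]
        const int b = 1 + (int)rng.below((uint64_t)window);
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= n) continue;
          const int context = sent[cpos] - 1;
          double* v_in = &syn0[(size_t)center * D];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = context; label = 1.0; }
            else {
              double r = rng.unif() * tot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= V) target = V - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * D];
            double dot = 0.0;
            for (int d = 0; d < D; ++d) dot += v_in[d] * v_out[d];
            const double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < D; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < D; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  Rcpp::NumericMatrix out(V, D);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < D; ++d)
      out(v, d) = syn0[(size_t)v * D + d];
  return out;
}
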