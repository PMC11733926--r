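// Skip-gram with negative sampling (word2vec-style) for substructure
// sentences. Single-threaded and driven by an internal xorshift RNG so
// that training is bit-reproducible for a given seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double unif() {  // in [0,1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size,
                         NumericVector counts, int dim, int window,
                         int epochs, int negative, double lr, int seed) {
  XorShift64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    tot += std::pow(counts[v], 0.75);
    cum[v] = tot;
  }

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.unif() - 0.5) / dim;
  }

  long long total_words = 0;
  const int n_sent = sentences.size();
  std::vector<std::vector<int> > sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector iv = sentences[s];
    sents[s].assign(iv.begin(), iv.end());
    total_words += iv.size();
  }
  const long long train_total = total_words * static_cast<long long>(epochs);
  long long processed = 0;

  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int>& sent = sents[s];
      const int len = static_cast<int>(sent.size());
      for (int pos = 0; pos < len; ++pos) {
        double alpha = lr * (1.0 - static_cast<double>(processed) /
                                       (train_total + 1));
        if (alpha < lr * 1e-4) alpha = lr * 1e-4;
        ++processed;
        const int b = static_cast<int>(rng.next() % window) + 1;
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          const int w = sent[pos];      // center: updates syn0
          const int c = sent[cpos];     // context/predicted: syn1
          double* v0 = &syn0[static_cast<size_t>(w) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = c;
              label = 1.0;
            } else {
              const double r = rng.unif() * tot;
              int lo = 0, hi = vocab_size - 1;
              while (lo < hi) {
                const int mid = (lo + hi) / 2;
                if (cum[mid] < r) lo = mid + 1; else hi = mid;
              }
              target = lo;
              if (target == c) continue;
              label = 0.0;
            }
            double* v1 = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v0[d] * v1[d];
            const double g = (label - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v1[d];
              v1[d] += g * v0[d];
            }
          }
          for (int d = 0; d < dim; ++d) v0[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v) {
    for (int d = 0; d < dim; ++d) {
      out(v, d) = syn0[static_cast<size_t>(v) * dim + d];
    }
  }
  return out;
}
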