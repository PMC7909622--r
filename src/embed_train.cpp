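// Word-embedding trainer (CBOW / skip-gram with negative sampling),
// following the canonical word2vec training scheme. Single-threaded and
// driven by an internal xorshift RNG so that a fixed seed reproduces the
// vector matrix bit-for-bit across runs and platforms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

// uniform double in [0, 1)
static inline double runif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static const double MAX_EXP = 6.0;

static inline double sigmoid(double x) {
  if (x > MAX_EXP) return 1.0;
  if (x < -MAX_EXP) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// sample a word index from the unigram^0.75 distribution via binary
// search over the cumulative table; used for negative sampling
static inline int sample_negative(const std::vector<double> &cum,
                                  uint64_t &rng) {
  double u = runif01(rng) * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] <= u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// docs: list of 0-based integer vectors (word indices per document)
// counts: vocabulary word frequencies (for the negative-sampling table)
// Returns the input-vector matrix, vocab_size x dim.
// [[Rcpp::export]]
NumericMatrix cpp_train_embedding(List docs, int vocab_size, int dim,
                                  int window, int negative, int epochs,
                                  double alpha, double min_alpha,
                                  double seed, bool cbow,
                                  NumericVector counts) {
  const int V = vocab_size, D = dim;
  uint64_t rng = (uint64_t)seed * 2654435761ULL + 88172645463325252ULL;
  for (int i = 0; i < 16; ++i) xorshift64(rng); // warm up

  std::vector<double> syn0((size_t)V * D), syn1((size_t)V * D, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (runif01(rng) - 0.5) / D;

  std::vector<double> cum(V);
  double acc = 0.0;
  for (int w = 0; w < V; ++w) {
    acc += std::pow(counts[w], 0.75);
    cum[w] = acc;
  }

  // pre-extract documents
  int n_docs = docs.size();
  std::vector<std::vector<int>> corpus(n_docs);
  long long total_words = 0;
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector v = docs[d];
    corpus[d].assign(v.begin(), v.end());
    total_words += v.size();
  }
  long long train_total = total_words * (long long)epochs;
  long long processed = 0;

  std::vector<double> h(D), e(D);
  std::vector<int> ctx;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      const std::vector<int> &doc = corpus[d];
      int n = (int)doc.size();
      for (int t = 0; t < n; ++t) {
        double lr = alpha * (1.0 - (double)processed / (double)(train_total + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++processed;
        int lo = t - window; if (lo < 0) lo = 0;
        int hi = t + window; if (hi > n - 1) hi = n - 1;
        ctx.clear();
        for (int j = lo; j <= hi; ++j)
          if (j != t) ctx.push_back(doc[j]);
        if (ctx.empty()) continue;
        int target = doc[t];

        if (cbow) {
          // hidden = mean of context input vectors
          std::fill(h.begin(), h.end(), 0.0);
          for (int c : ctx) {
            const double *row = &syn0[(size_t)c * D];
            for (int k = 0; k < D; ++k) h[k] += row[k];
          }
          double inv = 1.0 / ctx.size();
          for (int k = 0; k < D; ++k) h[k] *= inv;
          std::fill(e.begin(), e.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int tgt;
            double label;
            if (s == 0) { tgt = target; label = 1.0; }
            else {
              tgt = sample_negative(cum, rng);
              if (tgt == target) continue;
              label = 0.0;
            }
            double *orow = &syn1[(size_t)tgt * D];
            double f = 0.0;
            for (int k = 0; k < D; ++k) f += h[k] * orow[k];
            double g = (label - sigmoid(f)) * lr;
            for (int k = 0; k < D; ++k) {
              e[k] += g * orow[k];
              orow[k] += g * h[k];
            }
          }
          for (int c : ctx) {
            double *row = &syn0[(size_t)c * D];
            for (int k = 0; k < D; ++k) row[k] += e[k];
          }
        } else {
          // skip-gram: each context word predicts the center word
          for (int c : ctx) {
            double *row = &syn0[(size_t)c * D];
            std::fill(e.begin(), e.end(), 0.0);
            for (int s = 0; s <= negative; ++s) {
              int tgt;
              double label;
              if (s == 0) { tgt = target; label = 1.0; }
              else {
                tgt = sample_negative(cum, rng);
                if (tgt == target) continue;
                label = 0.0;
              }
              double *orow = &syn1[(size_t)tgt * D];
              double f = 0.0;
              for (int k = 0; k < D; ++k) f += row[k] * orow[k];
              double g = (label - sigmoid(f)) * lr;
              for (int k = 0; k < D; ++k) {
                e[k] += g * orow[k];
                orow[k] += g * row[k];
              }
            }
            for (int k = 0; k < D; ++k) row[k] += e[k];
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, D);
  for (int w = 0; w < V; ++w)
    for (int k = 0; k < D; ++k)
      out(w, k) = syn0[(size_t)w * D + k];
  return out;
}
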