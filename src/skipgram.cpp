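#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Skip-gram with negative sampling over mutation-token "sentences".
// Single-threaded with a self-contained xorshift64* generator so that the
// trained vectors are bit-identical for a given seed on any platform.

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// sentences: list of 0-based integer vectors (token ids per strain)
// counts: token frequencies (vocabulary order), for the 0.75-power
//         negative-sampling distribution
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(const List& sentences, const IntegerVector& counts,
                         int dim, int window, int epochs, int negative,
                         double lr_start, double lr_min, int seed) {
  const int vocab = counts.size();
  XorShift64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);

  // input (center) and output (context) vectors
  std::vector<double> syn0(static_cast<size_t>(vocab) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab) * dim, 0.0);
  for (size_t k = 0; k < syn0.size(); ++k)
    syn0[k] = (rng.unif() - 0.5) / dim;

  // cumulative count^0.75 table for negative sampling
  std::vector<double> cum(vocab);
  double tot = 0.0;
  for (int v = 0; v < vocab; ++v) { tot += std::pow((double)counts[v], 0.75); cum[v] = tot; }

  long long total_words = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total_words += Rf_length(VECTOR_ELT(sentences, s));
  total_words *= epochs;
  if (total_words == 0) stop("empty corpus");

  std::vector<double> grad(dim);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int len = sent.size();
      for (int t = 0; t < len; ++t) {
        double lr = lr_start - (lr_start - lr_min) *
                    (static_cast<double>(processed) / total_words);
        ++processed;
        const int center = sent[t];
        const int lo = std::max(0, t - window), hi = std::min(len - 1, t + window);
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          const int context = sent[c];
          double* v_in = &syn0[static_cast<size_t>(center) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int nsamp = 0; nsamp <= negative; ++nsamp) {
            int target; double label;
            if (nsamp == 0) { target = context; label = 1.0; }
            else {
              double u = rng.unif() * tot;
              target = static_cast<int>(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= vocab) target = vocab - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v_in[k] * v_out[k];
            const double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) grad[k] += g * v_out[k];
            for (int k = 0; k < dim; ++k) v_out[k] += g * v_in[k];
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
  return out;
}
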