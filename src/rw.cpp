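#include <Rcpp.h>
using namespace Rcpp;

// xorshift64* PRNG: platform-stable shuffling independent of R's RNG
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

// Fisher-Yates shuffle of idx using the local PRNG
static void shuffle_idx(std::vector<int> &idx, uint64_t &state) {
  for (int i = (int)idx.size() - 1; i > 0; --i) {
    int j = (int)(xorshift64(state) % (uint64_t)(i + 1));
    std::swap(idx[i], idx[j]);
  }
}

// Rescorla-Wagner tournament scoring: for each duel the predicted win
// probability is logistic(s_w - s_l); both scores move by alpha times the
// prediction error, symmetrically (zero-sum update).
// winner/loser are 1-based item indices.
// [[Rcpp::export]]
NumericVector rw_score_cpp(IntegerVector winner, IntegerVector loser,
                           int n_items, double alpha, int n_epochs,
                           double initial_score, bool shuffle,
                           double seed) {
  NumericVector s(n_items, initial_score);
  int n_duels = winner.size();
  std::vector<int> idx(n_duels);
  for (int i = 0; i < n_duels; ++i) idx[i] = i;
  uint64_t state = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  if (state == 0) state = 88172645463325252ULL;
  for (int e = 0; e < n_epochs; ++e) {
    if (shuffle) shuffle_idx(idx, state);
    for (int t = 0; t < n_duels; ++t) {
      int w = winner[idx[t]] - 1;
      int l = loser[idx[t]] - 1;
      double p = 1.0 / (1.0 + std::exp(-(s[w] - s[l])));
      double delta = alpha * (1.0 - p);
      s[w] += delta;
      s[l] -= delta;
    }
  }
  return s;
}
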