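// Ungapped X-drop extension of an exact seed along one diagonal of
// seq_a vs reverse_complement(seq_b).  Sequences are integer-encoded
// (A=1,C=2,G=3,T=4,N=0; N never matches).  Returns the extended block in
// 1-based coordinates on a / rc_b, with match count and score.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".extend_seed")]]
IntegerVector extend_seed(IntegerVector a, IntegerVector b,
                          int i, int j, int k,
                          int match_score, int mismatch_penalty,
                          int xdrop) {
  const int m = a.size(), n = b.size();
  // right of the seed
  int run = 0, best = 0, best_t = 0;
  for (int t = 1; i + k - 1 + t <= m && j + k - 1 + t <= n; ++t) {
    const int x = a[i + k - 2 + t], y = b[j + k - 2 + t];
    run += (x == y && x > 0) ? match_score : mismatch_penalty;
    if (run > best) { best = run; best_t = t; }
    else if (best - run > xdrop) break;
  }
  const int right = best_t;
  // left of the seed
  run = 0; best = 0; best_t = 0;
  for (int t = 1; i - t >= 1 && j - t >= 1; ++t) {
    const int x = a[i - t - 1], y = b[j - t - 1];
    run += (x == y && x > 0) ? match_score : mismatch_penalty;
    if (run > best) { best = run; best_t = t; }
    else if (best - run > xdrop) break;
  }
  const int left = best_t;

  const int s = i - left, e = i + k - 1 + right;   // 1-based on a
  int matches = 0;
  for (int t = 0; t < e - s + 1; ++t) {
    const int x = a[s - 1 + t], y = b[j - left - 1 + t];
    if (x == y && x > 0) ++matches;
  }
  const int len = e - s + 1;
  const int score = matches * match_score +
    (len - matches) * mismatch_penalty;
  return IntegerVector::create(s, e, j - left, matches, score);
}
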