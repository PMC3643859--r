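// Base-pair-maximisation secondary structure prediction (Nussinov DP)
// with a deterministic traceback.  Allowed pairs: AU/UA, GC/CG, GU/UG
// (sequences arrive DNA-normalised, so T stands for U); minimum hairpin
// loop length is configurable (default 3).  Traceback prefers pairing the
// 5'-most base, with the 5'-most legal partner among optimal choices.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>

static inline int encode(char c) {
  switch (c) {
  case 'A': return 1; case 'C': return 2;
  case 'G': return 3; case 'T': return 4;
  default:  return 0;  // N pairs nothing
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
Rcpp::List nussinov_fold(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  bool pair_ok[5][5];
  std::memset(pair_ok, 0, sizeof(pair_ok));
  pair_ok[1][4] = pair_ok[4][1] = true;  // A:T
  pair_ok[2][3] = pair_ok[3][2] = true;  // C:G
  pair_ok[3][4] = pair_ok[4][3] = true;  // G:T wobble

  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = encode(seq[i]);

  // dp is upper-triangular, flattened row-major: dp[i*n + j]
  std::vector<int> dp((size_t) n * n, 0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      const int *row_i1 = dp.data() + (size_t)(i + 1) * n;
      int best = row_i1[j];  // i unpaired
      const int ci = code[i];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!pair_ok[ci][code[k]]) continue;
        const int v = 1 + (k > i + 1 ? row_i1[k - 1] : 0) +
          (k < j ? dp[(size_t)(k + 1) * n + j] : 0);
        if (v > best) best = v;
      }
      dp[(size_t) i * n + j] = best;
    }
  }

  // deterministic traceback: pair i with the smallest optimal k, else
  // leave i unpaired
  std::string structure(n, '.');
  std::vector<std::pair<int,int>> stack;
  if (n > 0) stack.push_back({0, n - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_loop) continue;
    const int target = dp[(size_t) i * n + j];
    const int *row_i1 = dp.data() + (size_t)(i + 1) * n;
    const int ci = code[i];
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!pair_ok[ci][code[k]]) continue;
      const int v = 1 + (k > i + 1 ? row_i1[k - 1] : 0) +
        (k < j ? dp[(size_t)(k + 1) * n + j] : 0);
      if (v == target) {
        structure[i] = '(';
        structure[k] = ')';
        if (k - i > 1) stack.push_back({i + 1, k - 1});
        if (k < j) stack.push_back({k + 1, j});
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back({i + 1, j});
  }

  return Rcpp::List::create(
    Rcpp::Named("structure") = structure,
    Rcpp::Named("pairs") = n > 0 ? dp[n - 1] : 0);
}
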