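// Bulk degradome-window scanning: slide each reverse-complemented siRNA
// along each long-degradome window and report every offset with at most
// max_mismatch substitutions (no indels).  Mismatch positions are
// returned in siRNA coordinates (1 = 5' end, pairing the 3'-most site
// base).  'N' never matches.  Early exit once the budget is exceeded.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".scan_windows")]]
List scan_windows(CharacterVector windows, CharacterVector rc_sirnas,
                  IntegerVector sirna_lens, int max_mismatch,
                  bool gu_half) {
  std::vector<int> win_idx, q_idx, offset, n_mm;
  std::vector<std::vector<int>> mmpos_all;

  for (int w = 0; w < windows.size(); ++w) {
    const std::string win = as<std::string>(windows[w]);
    const int wlen = (int) win.size();
    for (int q = 0; q < rc_sirnas.size(); ++q) {
      const std::string rc = as<std::string>(rc_sirnas[q]);
      const int len = sirna_lens[q];
      if (len > wlen) continue;
      for (int off = 0; off <= wlen - len; ++off) {
        double weight = 0.0;
        std::vector<int> mm;
        bool over = false;
        for (int j = 0; j < len; ++j) {
          const char s = win[off + j], r = rc[j];
          if (s == r && s != 'N') continue;
          // wobble (siRNA G : site T  <=>  rc C : site T;
          //         siRNA T : site G  <=>  rc A : site G)
          bool wob = gu_half &&
            ((r == 'C' && s == 'T') || (r == 'A' && s == 'G'));
          weight += wob ? 0.5 : 1.0;
          if (weight > max_mismatch) { over = true; break; }
          if (!wob) mm.push_back(len - j);   // siRNA coordinate
        }
        if (over) continue;
        std::sort(mm.begin(), mm.end());
        win_idx.push_back(w + 1);
        q_idx.push_back(q + 1);
        offset.push_back(off);
        n_mm.push_back((int) mm.size());
        mmpos_all.push_back(mm);
      }
    }
  }

  List mmlist(mmpos_all.size());
  for (size_t i = 0; i < mmpos_all.size(); ++i) {
    mmlist[i] = IntegerVector(mmpos_all[i].begin(), mmpos_all[i].end());
  }
  return List::create(Named("win_idx") = wrap(win_idx),
                      Named("q_idx") = wrap(q_idx),
                      Named("offset") = wrap(offset),
                      Named("n_mismatch") = wrap(n_mm),
                      Named("mismatch_positions") = mmlist);
}
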