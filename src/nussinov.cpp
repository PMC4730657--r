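#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximization (Nussinov) with a minimum hairpin loop of 3 nt.
// Canonical pairs A:T, G:C plus the G:T wobble (T stands for U internally).
// Used as the deterministic folding fallback behind fold_sequences().

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// [[Rcpp::export(name = ".nussinov_fold")]]
std::string nussinov_fold(std::string seq, int min_loop = 3) {
  int n = seq.size();
  std::string db(n, '.');
  if (n < min_loop + 2) return db;
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i][j - 1];          // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (can_pair(seq[k], seq[j])) {
          int v = (k > i ? M[i][k - 1] : 0) + 1 +
                  (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
          if (v > best) best = v;
        }
      }
      M[i][j] = best;
    }
  }
  // iterative traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (M[i][j] == M[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(seq[k], seq[j])) continue;
      int v = (k > i ? M[i][k - 1] : 0) + 1 +
              (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
      if (v == M[i][j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return db;
}
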