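#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Maximum number of nested Watson-Crick/GU base pairs with a minimum
// hairpin loop of `min_loop` unpaired bases (Nussinov dynamic program).
// Sequence alphabet {A,C,G,T}; U must be mapped to T by the caller.
// [[Rcpp::export(name = ".nussinov_pairs")]]
int nussinov_pairs(const std::string& s, int min_loop = 3) {
  const int n = (int) s.size();
  for (int i = 0; i < n; ++i) {
    char c = s[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T')
      stop("sequence contains a base outside {A,C,G,T}");
  }
  if (n < min_loop + 2) return 0;
  std::vector<int> dp((size_t) n * n, 0);
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      int best = dp[(size_t)(i + 1) * n + j];  // base i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (can_pair(s[i], s[k])) {
          int v = 1 + dp[(size_t)(i + 1) * n + (k - 1)];
          if (k + 1 <= j) v += dp[(size_t)(k + 1) * n + j];
          if (v > best) best = v;
        }
      }
      dp[(size_t) i * n + j] = best;
    }
  }
  return dp[(size_t) 0 * n + (n - 1)];
}
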