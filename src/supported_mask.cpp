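#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Character positions of `cand` covered by a maximal common substring of
// length >= min_len shared with `note`. Inputs are integer code points
// (utf8ToInt on the R side) so the mask indexes characters, not bytes.
//
// Classic rolling-row DP: run[j] = length of the common suffix of
// cand[..i] and note[..j]; whenever a run reaches min_len its covered
// candidate positions are marked. Every common substring of length >= min_len
// lies inside a maximal one, so marking by runs yields exactly the union of
// maximal common substrings of length >= min_len.
// [[Rcpp::export(name = ".supported_mask_cpp")]]
LogicalVector supported_mask_cpp(IntegerVector cand, IntegerVector note,
                                 int min_len) {
  const int n = cand.size(), m = note.size();
  LogicalVector mask(n);
  if (n == 0 || m == 0 || min_len < 1) return mask;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (cand[i] == note[j - 1]) {
        const int L = prev[j - 1] + 1;
        cur[j] = L;
        if (L == min_len) {
          for (int k = i - min_len + 1; k <= i; ++k) mask[k] = true;
        } else if (L > min_len) {
          mask[i] = true;
        }
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return mask;
}
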