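#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Greedy selection of non-overlapping fixed-width windows by decreasing
// count, ties broken by leftmost start. `counts[s]` is the tag count of the
// window starting at 0-based position s (s = 0 .. L - width). Equivalent to
// repeatedly taking the highest-count window at 1-bp resolution and
// discarding every window overlapping a selected one. Windows with zero
// count are never selected.
//
// [[Rcpp::export]]
IntegerVector greedy_select_windows(NumericVector counts, int width) {
  const R_xlen_t n = counts.size();
  if (width < 1) stop("width must be >= 1");
  std::vector<R_xlen_t> idx;
  idx.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i)
    if (counts[i] > 0) idx.push_back(i);
  std::stable_sort(idx.begin(), idx.end(),
                   [&](R_xlen_t a, R_xlen_t b) {
                     if (counts[a] != counts[b]) return counts[a] > counts[b];
                     return a < b;
                   });
  std::vector<char> blocked(n, 0);
  std::vector<int> picked;
  for (R_xlen_t s : idx) {
    if (blocked[s]) continue;
    picked.push_back(static_cast<int>(s));
    R_xlen_t lo = std::max<R_xlen_t>(0, s - (width - 1));
    R_xlen_t hi = std::min<R_xlen_t>(n - 1, s + (width - 1));
    for (R_xlen_t j = lo; j <= hi; ++j) blocked[j] = 1;
  }
  std::sort(picked.begin(), picked.end());
  return wrap(picked);
}
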