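#include "core.h"
#include <algorithm>
#include <numeric>

// Weighted interval scheduling over half-open intervals [begin, end):
// classical predecessor DP after sorting by end. Two intervals conflict
// iff they share a position, so j is compatible before i iff end_j <= begin_i.
// Ties in the DP are broken toward including the current (later-ending)
// interval, deterministically.
std::vector<int> wis_solve(const std::vector<int> &begin,
                           const std::vector<int> &end,
                           const std::vector<double> &weight) {
  const int n = (int)begin.size();
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (end[a] != end[b]) return end[a] < end[b];
    return begin[a] < begin[b];
  });
  std::vector<int> ends_sorted(n);
  for (int i = 0; i < n; ++i) ends_sorted[i] = end[ord[i]];
  // pred[i]: largest sorted index j < i with end_j <= begin_i, else -1
  std::vector<int> pred(n);
  for (int i = 0; i < n; ++i) {
    int b = begin[ord[i]];
    int lo = std::upper_bound(ends_sorted.begin(), ends_sorted.begin() + i, b)
             - ends_sorted.begin();
    pred[i] = lo - 1;
  }
  std::vector<double> M(n + 1, 0.0);
  std::vector<char> take(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    double with = weight[ord[i - 1]] + M[pred[i - 1] + 1];
    double without = M[i - 1];
    if (with >= without) { M[i] = with; take[i] = 1; }
    else { M[i] = without; take[i] = 0; }
  }
  std::vector<int> sel;
  for (int i = n; i > 0;) {
    if (take[i]) { sel.push_back(ord[i - 1]); i = pred[i - 1] + 1; }
    else --i;
  }
  std::sort(sel.begin(), sel.end(), [&](int a, int b) {
    return begin[a] < begin[b];
  });
  return sel;
}
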