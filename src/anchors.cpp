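#include "core.h"
#include <deque>

// Positional minimizers: for every window start p in [0, L-k], the
// lexicographically smallest k-mer among start positions
// [p, min(p + w - k, L - k)]; leftmost position on ties; duplicates
// collapsed. Plain byte order, so A < C < G < N < T.
void minimizers_of(const std::string &seq, int k, int w,
                   std::vector<int> &pos_out) {
  pos_out.clear();
  const int L = (int)seq.size();
  if (L < k) return;
  const int nstart = L - k + 1;   // k-mer start positions
  const int span = w - k + 1;     // starts per window
  // monotone deque of candidate start positions; compare k-mers by bytes
  auto less_kmer = [&](int i, int j) {
    return seq.compare(i, k, seq, j, k) < 0;
  };
  std::deque<int> dq;
  int filled = 0;  // starts pushed so far
  for (int p = 0; p < nstart; ++p) {
    int hi = p + span - 1;
    if (hi > nstart - 1) hi = nstart - 1;
    while (filled <= hi) {
      // keep leftmost on ties: pop only strictly larger candidates
      while (!dq.empty() && less_kmer(filled, dq.back())) dq.pop_back();
      dq.push_back(filled);
      ++filled;
    }
    while (dq.front() < p) dq.pop_front();
    int best = dq.front();
    if (pos_out.empty() || pos_out.back() != best) pos_out.push_back(best);
  }
}
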