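#include "core.h"
#include <cstring>
#include <algorithm>

// Bit-parallel Levenshtein distance, block version (Myers 1999 / Hyyro 2003).
// Pattern = a (rows), text = b (columns).
int myers_ed(const std::string &a, const std::string &b) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  const int W = 64;
  const int blocks = (m + W - 1) / W;
  std::vector<uint64_t> peq(256 * (size_t)blocks, 0);
  for (int i = 0; i < m; ++i) {
    unsigned char c = (unsigned char)a[i];
    peq[(size_t)c * blocks + i / W] |= (uint64_t)1 << (i % W);
  }
  std::vector<uint64_t> Pv(blocks, ~(uint64_t)0), Mv(blocks, 0);
  int score = m;
  const uint64_t high = (uint64_t)1 << ((m - 1) % W);
  for (int j = 0; j < n; ++j) {
    const uint64_t *pe = &peq[(size_t)(unsigned char)b[j] * blocks];
    int hin = 1;  // boundary row D(0, j) = j increases by one per column
    for (int blk = 0; blk < blocks; ++blk) {
      uint64_t eq = pe[blk];
      uint64_t pv = Pv[blk], mv = Mv[blk];
      uint64_t xv = eq | mv;
      if (hin < 0) eq |= 1;
      uint64_t xh = (((eq & pv) + pv) ^ pv) | eq;
      uint64_t ph = mv | ~(xh | pv);
      uint64_t mh = pv & xh;
      int hout = 0;
      if (blk == blocks - 1) {
        if (ph & high) hout = 1;
        else if (mh & high) hout = -1;
      } else {
        if (ph >> (W - 1)) hout = 1;
        else if (mh >> (W - 1)) hout = -1;
      }
      ph <<= 1; mh <<= 1;
      if (hin < 0) mh |= 1;
      else if (hin > 0) ph |= 1;
      Pv[blk] = mh | ~(xv | ph);
      Mv[blk] = ph & xv;
      hin = hout;
    }
    score += hin;  // hout of the block holding the last pattern row
  }
  return score;
}

// Unit-cost global alignment with full DP and deterministic traceback.
// Preference on ties: diagonal, then gap in b (consume a), then gap in a.
void unit_align(const std::string &a, const std::string &b,
                std::string &out_a, std::string &out_b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1));
  // tb codes: 0 diag, 1 up (gap in b), 2 left (gap in a)
  for (int j = 0; j <= m; ++j) { prev[j] = j; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int up = prev[j] + 1;
      int left = cur[j - 1] + 1;
      int best = diag; uint8_t t = 0;
      if (up < best) { best = up; t = 1; }
      if (left < best) { best = left; t = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  // traceback
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && t == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (t == 1 || j == 0)) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  out_a = ra; out_b = rb;
}

AlnStats unit_align_stats(const std::string &read, const std::string &ref) {
  std::string ar, af;
  unit_align(read, ref, ar, af);
  AlnStats st{0, 0, 0, 0};
  for (size_t c = 0; c < ar.size(); ++c) {
    if (ar[c] == '-') ++st.del;            // base missing from read
    else if (af[c] == '-') ++st.ins;       // extra base in read
    else if (ar[c] == af[c]) ++st.matches;
    else ++st.subs;
  }
  return st;
}

std::string hc_compress(const std::string &s) {
  std::string out;
  out.reserve(s.size());
  for (size_t i = 0; i < s.size(); ++i)
    if (i == 0 || s[i] != s[i - 1]) out.push_back(s[i]);
  return out;
}
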