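#include "core.h"
#include <unordered_map>
#include <algorithm>

// Multi-alignment matrix from pairwise alignments of segments to the
// consensus. Insertions relative to the consensus are collected per
// junction (between consecutive consensus positions, plus both ends);
// each junction gets max-insertion-length columns, rows left-aligned,
// and the consensus row holds '-' there.
MsaMatrix build_msa(const std::vector<std::string> &segs,
                    const std::string &consensus) {
  const int L = (int)consensus.size();
  const int m = (int)segs.size();
  std::vector<std::vector<std::string>> ins(m, std::vector<std::string>(L + 1));
  std::vector<std::string> at(m, std::string(L, '-'));
  for (int t = 0; t < m; ++t) {
    std::string sa, sc;
    unit_align(segs[t], consensus, sa, sc);
    int cj = 0;
    for (size_t col = 0; col < sc.size(); ++col) {
      if (sc[col] != '-') {
        at[t][cj] = sa[col];
        ++cj;
      } else {
        ins[t][cj].push_back(sa[col]);
      }
    }
  }
  std::vector<int> width(L + 1, 0);
  for (int j = 0; j <= L; ++j)
    for (int t = 0; t < m; ++t)
      width[j] = std::max(width[j], (int)ins[t][j].size());
  MsaMatrix out;
  out.rows.assign(m, "");
  for (int j = 0; j <= L; ++j) {
    for (int t = 0; t < m; ++t) {
      std::string blk = ins[t][j];
      blk.resize(width[j], '-');
      out.rows[t] += blk;
      if (j < L) out.rows[t].push_back(at[t][j]);
    }
    out.consensus_row.append(width[j], '-');
    if (j < L) out.consensus_row.push_back(consensus[j]);
  }
  return out;
}

static std::string strip_gaps(const std::string &s) {
  std::string out;
  out.reserve(s.size());
  for (char c : s) if (c != '-') out.push_back(c);
  return out;
}

// Trusted contexts and variants per column. The consensus context is always
// trusted; any other context must occur in >= 3 rows and at least
// max(3, m*T / min(ed(c', b), ed(HC(c'), HC(b)))) times, with gap symbols
// stripped before edit distances; contexts identical to the consensus
// context under homopolymer compression are not considered.
std::vector<std::vector<Trusted>> trusted_sets_of(const MsaMatrix &mat,
                                                  int k, double T) {
  const int m = (int)mat.rows.size();
  const int ncol = (int)mat.consensus_row.size();
  std::vector<std::vector<Trusted>> out(ncol);
  std::unordered_map<std::string, int> count_of;
  std::vector<std::string> order;
  for (int j = 0; j < ncol; ++j) {
    int lo, hi;
    window_bounds(j, ncol, k, lo, hi);
    const int wlen = hi - lo + 1;
    count_of.clear();
    order.clear();
    for (int t = 0; t < m; ++t) {
      std::string wctx = mat.rows[t].substr(lo, wlen);
      auto it = count_of.find(wctx);
      if (it == count_of.end()) {
        count_of.emplace(std::move(wctx), 1);
        order.push_back(mat.rows[t].substr(lo, wlen));
      } else {
        ++it->second;
      }
    }
    std::string cctx = mat.consensus_row.substr(lo, wlen);
    int ccount = 0;
    auto itc = count_of.find(cctx);
    if (itc != count_of.end()) ccount = itc->second;
    std::vector<Trusted> trust;
    trust.push_back({cctx, cctx[j - lo], ccount, true});
    std::string c_strip = strip_gaps(cctx);
    std::string c_hc = hc_compress(c_strip);
    for (const std::string &b : order) {
      if (b == cctx) continue;
      int cnt = count_of[b];
      if (cnt < 3) continue;
      std::string b_strip = strip_gaps(b);
      std::string b_hc = hc_compress(b_strip);
      int d1 = myers_ed(c_strip, b_strip);
      int d2 = myers_ed(c_hc, b_hc);
      int den = std::min(d1, d2);
      if (den == 0) continue;  // homopolymer-length-only difference
      double thr = std::max(3.0, (double)m * T / den);
      if ((double)cnt >= thr) trust.push_back({b, b[j - lo], cnt, false});
    }
    out[j] = std::move(trust);
  }
  return out;
}

// Correct one row against per-column trusted variants; all decisions are
// taken against the original row, then applied at once. Ties on context
// distance prefer the higher-count context, then the consensus context.
std::string correct_row_syms(const std::string &row,
                             const std::vector<std::vector<Trusted>> &trust,
                             int k) {
  const int ncol = (int)row.size();
  std::string out = row;
  for (int j = 0; j < ncol; ++j) {
    const std::vector<Trusted> &tr = trust[j];
    int lo, hi;
    window_bounds(j, ncol, k, lo, hi);
    std::string wctx = row.substr(lo, hi - lo + 1);
    if (tr.size() == 1 && wctx == tr[0].context) continue;
    std::string w_strip = strip_gaps(wctx);
    int best = -1, best_d = 0;
    for (size_t t = 0; t < tr.size(); ++t) {
      int d = (wctx == tr[t].context)
                  ? 0
                  : myers_ed(w_strip, strip_gaps(tr[t].context));
      if (best < 0 || d < best_d ||
          (d == best_d && tr[t].count > tr[best].count) ||
          (d == best_d && tr[t].count == tr[best].count && tr[t].is_consensus))
        { best = (int)t; best_d = d; }
    }
    out[j] = tr[best].variant;
  }
  return out;
}
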