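#include "core.h"
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ----- shared helpers --------------------------------------------------

// 3-bit encoding preserving byte order A < C < G < N < T
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'N': return 3;
    case 'T': return 4;
    default: return 3;
  }
}

static inline uint64_t kmer_code(const std::string &s, int p, int k) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) v = (v << 3) | (uint64_t)base_code(s[p + i]);
  return v;
}

struct Occ { int32_t read, p, q; };

// banded global-alignment prefix DP between A[0..LA) and B[0..LB): all
// prefix distances with |i - j| <= D are exact; values above D are capped.
struct BandDP {
  int LA, LB, D, W;
  std::vector<int> M;  // (LA+1) x (2D+1)
  void run(const char *A, int LA_, const char *B, int LB_, int D_) {
    LA = LA_; LB = LB_; D = D_; W = 2 * D + 1;
    const int INF = 1 << 28;
    M.assign((size_t)(LA + 1) * W, INF);
    for (int d = D; d < W; ++d) {
      int j = d - D;
      if (j <= LB) M[d] = j;
    }
    for (int i = 1; i <= LA; ++i) {
      int *row = &M[(size_t)i * W];
      const int *up = &M[(size_t)(i - 1) * W];
      for (int d = 0; d < W; ++d) {
        int j = i + d - D;
        if (j < 0 || j > LB) continue;
        int best;
        if (j == 0) best = i;
        else {
          best = up[d] + (A[i - 1] == B[j - 1] ? 0 : 1);  // diagonal
          int v = (d + 1 < W) ? up[d + 1] + 1 : INF;       // (i-1, j)
          if (v < best) best = v;
          v = (d > 0) ? row[d - 1] + 1 : INF;              // (i, j-1)
          if (v < best) best = v;
        }
        row[d] = best;
      }
    }
  }
};

// capped values are still valid upper bounds of the true distance
static inline int band_cell(const BandDP &b, int i, int j) {
  int d = j - i + b.D;
  if (d < 0 || d >= b.W) return b.D + 1 + std::abs(j - i);
  return b.M[(size_t)i * b.W + d];
}

// ----- cluster correction ----------------------------------------------

namespace {

struct CacheEnt { int begin, end, support; std::string inner; };

struct Candidate {
  int p, q;           // anchor start positions
  int support;        // resolved support (>= 1)
  bool resolved;      // support known without edit-distance sweep (cache)
  int exact_cache;    // index into the read's cache entries, or -1
  std::vector<Occ> segs;  // passing supporting occurrences (other reads)
};

struct Cluster {
  std::vector<std::string> seq;
  std::vector<std::vector<double>> qcum;  // prefix sums of error probs
  int k, w, xmin, xmax, max_spoa;
  double T;
  std::unordered_map<uint64_t, std::vector<Occ>> index;
  std::vector<std::vector<int>> minis;

  double eps(int r, int a, int b) const {  // mean error prob over [a, b)
    return (qcum[r][b] - qcum[r][a]) / (b - a);
  }
  std::string segment(const Occ &o) const {
    return seq[o.read].substr(o.p, o.q + k - o.p);
  }
};

uint64_t pair_key(const Cluster &C, int r, int pa, int pb) {
  return (kmer_code(C.seq[r], pa, C.k) << (3 * C.k)) |
         kmer_code(C.seq[r], pb, C.k);
}

bool all_a(const std::string &s, int p, int k) {
  for (int i = 0; i < k; ++i) if (s[p + i] != 'A') return false;
  return true;
}

void build_index(Cluster &C) {
  const int n = (int)C.seq.size();
  C.minis.resize(n);
  for (int r = 0; r < n; ++r) {
    minimizers_of(C.seq[r], C.k, C.w, C.minis[r]);
    const std::vector<int> &mp = C.minis[r];
    for (size_t a = 0; a < mp.size(); ++a) {
      bool a_allA = all_a(C.seq[r], mp[a], C.k);
      for (size_t b = a + 1; b < mp.size(); ++b) {
        int gap = mp[b] - mp[a];
        if (gap < C.xmin) continue;
        if (gap > C.xmax) break;
        if (a_allA && all_a(C.seq[r], mp[b], C.k)) continue;
        C.index[pair_key(C, r, mp[a], mp[b])].push_back({r, mp[a], mp[b]});
      }
    }
  }
}

// enumerate candidate intervals of read r (same masking as the index)
void enumerate_candidates(const Cluster &C, int r,
                          std::vector<Candidate> &out) {
  out.clear();
  const std::vector<int> &mp = C.minis[r];
  for (size_t a = 0; a < mp.size(); ++a) {
    bool a_allA = all_a(C.seq[r], mp[a], C.k);
    for (size_t b = a + 1; b < mp.size(); ++b) {
      int gap = mp[b] - mp[a];
      if (gap < C.xmin) continue;
      if (gap > C.xmax) break;
      if (a_allA && all_a(C.seq[r], mp[b], C.k)) continue;
      out.push_back({mp[a], mp[b], 1, false, -1, {}});
    }
  }
}

// support of one candidate by direct per-occurrence edit distances
void support_direct(const Cluster &C, int r, Candidate &c) {
  auto it = C.index.find(pair_key(C, r, c.p, c.q));
  if (it == C.index.end()) return;
  const std::string s = C.seq[r].substr(c.p, c.q + C.k - c.p);
  const double eps_s = C.eps(r, c.p, c.q + C.k);
  const std::vector<Occ> &occ = it->second;
  size_t i = 0;
  while (i < occ.size()) {
    int rd = occ[i].read;
    if (rd == r) { ++i; continue; }
    int best_ed = -1; Occ best{};
    while (i < occ.size() && occ[i].read == rd) {
      std::string sp = C.segment(occ[i]);
      int ed = myers_ed(s, sp);
      if (best_ed < 0 || ed < best_ed) { best_ed = ed; best = occ[i]; }
      ++i;
    }
    double thr = (double)s.size() *
                 (eps_s + C.eps(rd, best.p, best.q + C.k));
    // guard against floating-point noise at the exact boundary
    if ((double)best_ed < thr - 1e-9) { ++c.support; c.segs.push_back(best); }
  }
}

// support for all unresolved candidates of read r via grouped banded DP:
// candidates sharing a left anchor position p and an occurrence site
// (read', p') are scored with one banded prefix DP.
void support_sweep(const Cluster &C, int r, std::vector<Candidate> &cands) {
  struct Entry { int cand; int q2; };
  std::unordered_map<uint64_t, std::vector<Entry>> buckets;
  struct Hit { int read, p2, q2, ed; };
  std::vector<std::vector<Hit>> hits(cands.size());
  BandDP dp;
  size_t i0 = 0;
  while (i0 < cands.size()) {
    size_t i1 = i0;
    int p = cands[i0].p;
    while (i1 < cands.size() && cands[i1].p == p) ++i1;
    buckets.clear();
    for (size_t c = i0; c < i1; ++c) {
      if (cands[c].resolved) continue;
      auto it = C.index.find(pair_key(C, r, cands[c].p, cands[c].q));
      if (it == C.index.end()) continue;
      for (const Occ &o : it->second) {
        if (o.read == r) continue;
        buckets[((uint64_t)o.read << 32) | (uint32_t)o.p]
            .push_back({(int)c, o.q});
      }
    }
    for (auto &kv : buckets) {
      int rd = (int)(kv.first >> 32);
      int p2 = (int)(uint32_t)kv.first;
      int LA = 0, LB = 0, D = 1;
      for (const Entry &e : kv.second) {
        int la = cands[e.cand].q + C.k - p;
        int lb = e.q2 + C.k - p2;
        LA = std::max(LA, la);
        LB = std::max(LB, lb);
        double thr = la * (C.eps(r, p, p + la) + C.eps(rd, p2, p2 + lb));
        D = std::max(D, (int)std::ceil(thr));
      }
      D = std::min(D, std::max(LA, LB));
      dp.run(C.seq[r].data() + p, LA, C.seq[rd].data() + p2, LB, D);
      for (const Entry &e : kv.second) {
        int la = cands[e.cand].q + C.k - p;
        int lb = e.q2 + C.k - p2;
        hits[e.cand].push_back({rd, p2, e.q2, band_cell(dp, la, lb)});
      }
    }
    i0 = i1;
  }
  for (size_t c = 0; c < cands.size(); ++c) {
    if (cands[c].resolved || hits[c].empty()) continue;
    std::vector<Hit> &h = hits[c];
    std::sort(h.begin(), h.end(), [](const Hit &a, const Hit &b) {
      if (a.read != b.read) return a.read < b.read;
      if (a.ed != b.ed) return a.ed < b.ed;
      if (a.p2 != b.p2) return a.p2 < b.p2;
      return a.q2 < b.q2;
    });
    int sl = cands[c].q + C.k - cands[c].p;
    double eps_s = C.eps(r, cands[c].p, cands[c].q + C.k);
    for (size_t t = 0; t < h.size();) {
      const Hit &best = h[t];
      double thr = (double)sl *
                   (eps_s + C.eps(best.read, best.p2, best.q2 + C.k));
      if ((double)best.ed < thr - 1e-9) {
        ++cands[c].support;
        cands[c].segs.push_back({best.read, best.p2, best.q2});
      }
      int rd = best.read;
      while (t < h.size() && h[t].read == rd) ++t;
    }
  }
}

// inner column range of a row: columns strictly between the row's base
// k-1 and base (nbase - k); bases outside it are the anchor k-mers.
void inner_col_range(const std::string &row, int k, int &colL, int &colR) {
  int nbase = 0;
  for (char ch : row) if (ch != '-') ++nbase;
  int idxL = k - 1, idxR = nbase - k;
  int cnt = -1;
  colL = -1; colR = (int)row.size();
  for (int col = 0; col < (int)row.size(); ++col) {
    if (row[col] == '-') continue;
    ++cnt;
    if (cnt == idxL) colL = col;
    if (cnt == idxR) { colR = col; break; }
  }
}

std::string inner_corrected(const std::string &orig_row,
                            const std::string &corr_syms, int k) {
  int colL, colR;
  inner_col_range(orig_row, k, colL, colR);
  std::string out;
  for (int col = colL + 1; col < colR; ++col)
    if (corr_syms[col] != '-') out.push_back(corr_syms[col]);
  return out;
}

}  // namespace

// support of one interval, by direct per-occurrence edit distances
// (independent of the banded sweep used inside cluster correction)
// [[Rcpp::export(name = ".cpp_compute_support")]]
List cpp_compute_support(CharacterVector seqs, List quals, int read1,
                         int p, int q, int k, int w, int xmin, int xmax) {
  const int n = seqs.size();
  Cluster C;
  C.k = k; C.w = w; C.xmin = xmin; C.xmax = xmax;
  C.T = 0.1; C.max_spoa = 200;
  C.seq.resize(n);
  C.qcum.resize(n);
  for (int i = 0; i < n; ++i) {
    C.seq[i] = as<std::string>(seqs[i]);
    NumericVector qv = quals[i];
    C.qcum[i].resize(qv.size() + 1);
    C.qcum[i][0] = 0.0;
    for (int j = 0; j < qv.size(); ++j)
      C.qcum[i][j + 1] = C.qcum[i][j] + qv[j];
  }
  build_index(C);
  int r = read1 - 1;
  Candidate c{p, q, 1, false, -1, {}};
  auto itk = C.index.find(pair_key(C, r, p, q));
  bool found = false;
  if (itk != C.index.end())
    for (const Occ &o : itk->second)
      if (o.read == r && o.p == p && o.q == q) { found = true; break; }
  if (!found) stop("anchor pair not found on the read");
  support_direct(C, r, c);
  IntegerMatrix segs((int)c.segs.size() + 1, 3);
  segs(0, 0) = r + 1; segs(0, 1) = p; segs(0, 2) = q;
  for (size_t t = 0; t < c.segs.size(); ++t) {
    segs((int)t + 1, 0) = c.segs[t].read + 1;
    segs((int)t + 1, 1) = c.segs[t].p;
    segs((int)t + 1, 2) = c.segs[t].q;
  }
  colnames(segs) = CharacterVector::create("read", "p", "q");
  return List::create(_["support"] = c.support,
                      _["weight"] = (double)c.support * (q - p - k),
                      _["segments"] = segs);
}

// [[Rcpp::export(name = ".cpp_correct_cluster")]]
List cpp_correct_cluster(CharacterVector seqs, List quals, int k, int w,
                         int xmin, int xmax, double T, int max_seq_to_spoa,
                         bool approximate, bool details, int only_read = 0) {
  const int n = seqs.size();
  Cluster C;
  C.k = k; C.w = w; C.xmin = xmin; C.xmax = xmax;
  C.T = T; C.max_spoa = max_seq_to_spoa;
  C.seq.resize(n);
  C.qcum.resize(n);
  for (int i = 0; i < n; ++i) {
    C.seq[i] = as<std::string>(seqs[i]);
    NumericVector q = quals[i];
    C.qcum[i].resize(q.size() + 1);
    C.qcum[i][0] = 0.0;
    for (int j = 0; j < q.size(); ++j) C.qcum[i][j + 1] = C.qcum[i][j] + q[j];
  }
  build_index(C);

  std::vector<std::vector<CacheEnt>> cache(n);
  CharacterVector corrected(n);
  List sel_details(details ? n : 0);
  int anchorless = 0;
  std::vector<Candidate> cands;

  for (int r = 0; r < n; ++r) {
    if (only_read > 0 && r != only_read - 1) {
      corrected[r] = C.seq[r];
      continue;
    }
    enumerate_candidates(C, r, cands);
    if (cands.empty()) {
      corrected[r] = C.seq[r];
      ++anchorless;
      if (details) sel_details[r] = IntegerMatrix(0, 3);
      continue;
    }
    // approximate mode: previously processed regions of this read enter the
    // scheduling instance directly with their stored support; candidate
    // intervals overlapping a processed region are not recomputed.
    if (approximate && !cache[r].empty()) {
      const std::vector<CacheEnt> &ce = cache[r];
      std::vector<std::pair<int, int>> spans;
      std::vector<Candidate> kept;
      kept.reserve(cands.size());
      for (size_t t = 0; t < ce.size(); ++t) {
        bool dup = false;
        for (const auto &sp : spans)
          if (sp.first == ce[t].begin && sp.second == ce[t].end)
            { dup = true; break; }
        if (dup) continue;  // keep the first-stored corrected substring
        spans.push_back({ce[t].begin, ce[t].end});
        kept.push_back({ce[t].begin - k, ce[t].end, ce[t].support,
                        true, (int)t, {}});
      }
      for (const Candidate &c : cands) {
        int begin = c.p + k, end = c.q;
        bool covered = false;
        for (const auto &sp : spans)
          if (std::min(end, sp.second) > std::max(begin, sp.first))
            { covered = true; break; }
        if (!covered) kept.push_back(c);
      }
      // keep candidates grouped by left anchor for the support sweep
      std::stable_sort(kept.begin(), kept.end(),
                       [](const Candidate &a, const Candidate &b) {
                         return a.p < b.p;
                       });
      cands.swap(kept);
    }
    support_sweep(C, r, cands);
    // weighted interval scheduling
    std::vector<int> vb(cands.size()), ve(cands.size());
    std::vector<double> vw(cands.size());
    for (size_t c = 0; c < cands.size(); ++c) {
      vb[c] = cands[c].p + k;
      ve[c] = cands[c].q;
      vw[c] = (double)cands[c].support * (ve[c] - vb[c]);
    }
    std::vector<int> sel = wis_solve(vb, ve, vw);
    // correct selected intervals
    std::string out;
    out.reserve(C.seq[r].size() + 16);
    int cursor = 0;
    IntegerMatrix det(details ? (int)sel.size() : 0, 3);
    for (size_t si = 0; si < sel.size(); ++si) {
      Candidate &c = cands[sel[si]];
      int begin = c.p + k, end = c.q;
      out.append(C.seq[r], cursor, begin - cursor);
      cursor = end;
      if (details) { det(si, 0) = begin; det(si, 1) = end; det(si, 2) = c.support; }
      if (approximate && c.exact_cache >= 0) {
        out += cache[r][c.exact_cache].inner;
        continue;
      }
      if (c.segs.empty()) {  // no support beyond the read itself
        out.append(C.seq[r], begin, end - begin);
        continue;
      }
      std::vector<std::string> segs;
      segs.reserve(c.segs.size() + 1);
      segs.push_back(C.seq[r].substr(c.p, c.q + k - c.p));
      for (const Occ &o : c.segs) segs.push_back(C.segment(o));
      int m = (int)segs.size();
      std::vector<std::string> spoa_in(
          segs.begin(), segs.begin() + std::min(m, C.max_spoa));
      std::string cons = poa_consensus(spoa_in);
      MsaMatrix mat = build_msa(segs, cons);
      std::vector<std::vector<Trusted>> trust = trusted_sets_of(mat, k, C.T);
      std::string syms0 = correct_row_syms(mat.rows[0], trust, k);
      out += inner_corrected(mat.rows[0], syms0, k);
      if (approximate) {
        for (int t = 1; t < m; ++t) {
          const Occ &o = c.segs[t - 1];
          if (o.read <= r) continue;  // already corrected
          std::string syms = correct_row_syms(mat.rows[t], trust, k);
          cache[o.read].push_back(
              {o.p + k, o.q, m, inner_corrected(mat.rows[t], syms, k)});
        }
      }
    }
    out.append(C.seq[r], cursor, C.seq[r].size() - cursor);
    corrected[r] = out;
    if (details) sel_details[r] = det;
  }
  List res = List::create(_["corrected"] = corrected,
                          _["n_no_anchors"] = anchorless);
  if (details) res["intervals"] = sel_details;
  return res;
}
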