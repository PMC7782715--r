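#include "core.h"
#include <algorithm>
#include <limits>

// Partial-order alignment for consensus calling of short, similar segments.
// Sequences are threaded one by one through a DAG by global alignment to the
// graph: equal bases fuse with the aligned node, mismatches and insertions
// create nodes, deletions skip nodes. Edge weights count the sequences using
// the edge; the consensus is the heaviest source-to-sink bundle.

namespace {

const int MATCH = 2, MISMATCH = -4, GAP = -4;
const long long NEG = std::numeric_limits<long long>::min() / 4;

struct Graph {
  std::vector<char> base;
  std::vector<std::vector<int>> in_nodes;
  std::vector<std::vector<int>> in_w;
  std::vector<int> out_count;
  std::vector<int> start_w, end_w;
  std::vector<int> topo;   // node ids, topological order
  std::vector<int> rank;   // rank[id] = position in topo

  int add_node(char c) {
    base.push_back(c);
    in_nodes.emplace_back();
    in_w.emplace_back();
    out_count.push_back(0);
    start_w.push_back(0);
    end_w.push_back(0);
    rank.push_back(-1);
    return (int)base.size() - 1;
  }
  void insert_topo(int v, int pos) {  // v gets rank pos
    topo.insert(topo.begin() + pos, v);
    for (int t = pos; t < (int)topo.size(); ++t) rank[topo[t]] = t;
  }
  void add_edge(int u, int v) {
    auto &ins = in_nodes[v];
    for (size_t t = 0; t < ins.size(); ++t)
      if (ins[t] == u) { ++in_w[v][t]; return; }
    ins.push_back(u);
    in_w[v].push_back(1);
    ++out_count[u];
  }
};

void thread_seq(Graph &g, const std::string &s) {
  const int m = (int)s.size();
  if (m == 0) return;
  if (g.base.empty()) {
    int prev = -1;
    for (int i = 0; i < m; ++i) {
      int v = g.add_node(s[i]);
      g.insert_topo(v, (int)g.topo.size());
      if (prev >= 0) g.add_edge(prev, v); else ++g.start_w[v];
      prev = v;
    }
    ++g.end_w[prev];
    return;
  }
  const int N = (int)g.topo.size();
  // ranks 1..N are nodes topo[r-1]; rank 0 is the virtual source.
  // S[r][j]: best score with node r consumed last and j seq chars consumed.
  const int R = N + 1;
  std::vector<long long> S((size_t)R * (m + 1), NEG);
  std::vector<uint8_t> mv((size_t)R * (m + 1), 0);  // 1 diag, 2 del, 3 ins
  std::vector<int> frm((size_t)R * (m + 1), 0);
  auto idx = [&](int r, int j) { return (size_t)r * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) {  // virtual source row: leading insertions
    S[idx(0, j)] = (long long)j * GAP;
    mv[idx(0, j)] = j ? 3 : 0;
    frm[idx(0, j)] = 0;
  }
  for (int r = 1; r <= N; ++r) {
    int v = g.topo[r - 1];
    // predecessor ranks (virtual source for start nodes)
    std::vector<int> preds;
    if (g.in_nodes[v].empty()) preds.push_back(0);
    else for (int u : g.in_nodes[v]) preds.push_back(g.rank[u] + 1);
    for (int j = 0; j <= m; ++j) {
      long long best = NEG; uint8_t bm = 0; int bf = 0;
      for (int pr : preds) {
        if (j >= 1 && S[idx(pr, j - 1)] > NEG) {
          long long cand = S[idx(pr, j - 1)] +
                           (s[j - 1] == g.base[v] ? MATCH : MISMATCH);
          if (cand > best) { best = cand; bm = 1; bf = pr; }
        }
        if (S[idx(pr, j)] > NEG) {
          long long cand = S[idx(pr, j)] + GAP;
          if (cand > best) { best = cand; bm = 2; bf = pr; }
        }
      }
      S[idx(r, j)] = best; mv[idx(r, j)] = bm; frm[idx(r, j)] = bf;
    }
    for (int j = 1; j <= m; ++j) {  // insertions at this node
      if (S[idx(r, j - 1)] > NEG && S[idx(r, j - 1)] + GAP > S[idx(r, j)]) {
        S[idx(r, j)] = S[idx(r, j - 1)] + GAP;
        mv[idx(r, j)] = 3; frm[idx(r, j)] = r;
      }
    }
  }
  // terminal: best sink (no out-edges, or a sequence ended there)
  int best_r = 0; long long best_sc = NEG;
  for (int r = 1; r <= N; ++r) {
    int v = g.topo[r - 1];
    if (g.out_count[v] > 0 && g.end_w[v] == 0) continue;
    if (S[idx(r, m)] > best_sc) { best_sc = S[idx(r, m)]; best_r = r; }
  }
  if (best_r == 0) {  // degenerate; end anywhere
    for (int r = 1; r <= N; ++r)
      if (S[idx(r, m)] > best_sc) { best_sc = S[idx(r, m)]; best_r = r; }
  }
  // traceback into an op list (reversed)
  struct Op { uint8_t type; int node; int j; };  // type as in mv
  std::vector<Op> ops;
  int r = best_r, j = m;
  while (r != 0 || j != 0) {
    uint8_t t = mv[idx(r, j)];
    int f = frm[idx(r, j)];
    if (t == 1) { ops.push_back({1, g.topo[r - 1], j - 1}); r = f; --j; }
    else if (t == 2) { ops.push_back({2, g.topo[r - 1], -1}); r = f; }
    else if (t == 3) { ops.push_back({3, -1, j - 1}); --j; }
    else break;
  }
  std::reverse(ops.begin(), ops.end());
  // thread the sequence along the traceback
  int prev = -1;
  for (const Op &op : ops) {
    if (op.type == 2) continue;  // node skipped by this sequence
    int v;
    if (op.type == 1 && s[op.j] == g.base[op.node]) {
      v = op.node;  // fuse
    } else if (op.type == 1) {
      v = g.add_node(s[op.j]);  // mismatch sibling, placed just after anchor
      g.insert_topo(v, g.rank[op.node] + 1);
    } else {
      v = g.add_node(s[op.j]);  // insertion, placed just after prev
      g.insert_topo(v, prev >= 0 ? g.rank[prev] + 1 : 0);
    }
    if (prev >= 0) g.add_edge(prev, v); else ++g.start_w[v];
    prev = v;
  }
  if (prev >= 0) ++g.end_w[prev];
}

}  // namespace

std::string poa_consensus(const std::vector<std::string> &segs) {
  Graph g;
  for (const auto &s : segs) thread_seq(g, s);
  const int N = (int)g.topo.size();
  if (N == 0) return "";
  std::vector<long long> sc(g.base.size(), NEG);
  std::vector<int> prev(g.base.size(), -1);
  for (int r = 0; r < N; ++r) {
    int v = g.topo[r];
    long long best = g.start_w[v] > 0 ? (long long)g.start_w[v] : NEG;
    int bp = -1;
    for (size_t t = 0; t < g.in_nodes[v].size(); ++t) {
      int u = g.in_nodes[v][t];
      if (sc[u] <= NEG) continue;
      long long cand = sc[u] + g.in_w[v][t];
      if (cand > best) { best = cand; bp = u; }
    }
    sc[v] = best; prev[v] = bp;
  }
  long long best = NEG; int bv = -1;
  for (int r = 0; r < N; ++r) {
    int v = g.topo[r];
    if (g.end_w[v] == 0 || sc[v] <= NEG) continue;
    long long cand = sc[v] + g.end_w[v];
    if (cand > best) { best = cand; bv = v; }
  }
  std::string out;
  for (int v = bv; v >= 0; v = prev[v]) out.push_back(g.base[v]);
  std::reverse(out.begin(), out.end());
  return out;
}
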