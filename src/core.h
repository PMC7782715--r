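#ifndef ANCHORCORRECT_CORE_H
#define ANCHORCORRECT_CORE_H

#include <string>
#include <vector>
#include <cstdint>

// exact Levenshtein distance (bit-parallel, any lengths)
int myers_ed(const std::string &a, const std::string &b);

// unit-cost global alignment; returns aligned strings with '-' gaps.
// Deterministic traceback: diagonal > gap-in-b (deletion) > gap-in-a.
void unit_align(const std::string &a, const std::string &b,
                std::string &out_a, std::string &out_b);

// per-column alignment statistics against a reference
struct AlnStats {
  int matches, subs, ins, del;
  int aln_len() const { return matches + subs + ins + del; }
  int mismatches() const { return subs + ins + del; }
};
AlnStats unit_align_stats(const std::string &read, const std::string &ref);

// homopolymer compression
std::string hc_compress(const std::string &s);

// positional minimizers: distinct (pos) of window minimizers, increasing pos
void minimizers_of(const std::string &seq, int k, int w,
                   std::vector<int> &pos_out);

// partial-order-alignment consensus (heaviest bundle over edge weights)
std::string poa_consensus(const std::vector<std::string> &segs);

// multi-alignment matrix of segments against a consensus
struct MsaMatrix {
  std::vector<std::string> rows;  // one per segment, equal widths
  std::string consensus_row;      // '-' at insertion columns
};
MsaMatrix build_msa(const std::vector<std::string> &segs,
                    const std::string &consensus);

// trusted contexts/variants of one column window
struct Trusted {
  std::string context;  // matrix symbols incl '-'
  char variant;
  int count;
  bool is_consensus;
};
// window bounds in matrix column space for column j
inline void window_bounds(int j, int ncol, int k, int &lo, int &hi) {
  int h = k / 2;
  lo = j - h; if (lo < 0) lo = 0;
  hi = j + h; if (hi > ncol - 1) hi = ncol - 1;
}
std::vector<std::vector<Trusted>> trusted_sets_of(const MsaMatrix &m,
                                                  int k, double T);
// corrected symbols of one row (gaps retained); decisions taken per column
// against the original row
std::string correct_row_syms(const std::string &row,
                             const std::vector<std::vector<Trusted>> &trust,
                             int k);

// weighted interval scheduling: returns indices of an optimal subset of
// non-overlapping half-open intervals, ordered by begin
std::vector<int> wis_solve(const std::vector<int> &begin,
                           const std::vector<int> &end,
                           const std::vector<double> &weight);

#endif
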