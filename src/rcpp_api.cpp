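#include "core.h"
#include <Rcpp.h>

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_edit_distance")]]
int cpp_edit_distance(std::string a, std::string b) {
  return myers_ed(a, b);
}

// [[Rcpp::export(name = ".cpp_edit_distance_many")]]
IntegerVector cpp_edit_distance_many(std::string a,
                                     std::vector<std::string> bs) {
  IntegerVector out(bs.size());
  for (size_t i = 0; i < bs.size(); ++i) out[i] = myers_ed(a, bs[i]);
  return out;
}

// [[Rcpp::export(name = ".cpp_global_align")]]
CharacterVector cpp_global_align(std::string a, std::string b) {
  std::string oa, ob;
  unit_align(a, b, oa, ob);
  return CharacterVector::create(oa, ob);
}

// [[Rcpp::export(name = ".cpp_align_stats")]]
IntegerVector cpp_align_stats(std::string read, std::string ref) {
  AlnStats st = unit_align_stats(read, ref);
  return IntegerVector::create(_["matches"] = st.matches,
                               _["subs"] = st.subs, _["ins"] = st.ins,
                               _["del"] = st.del,
                               _["aln_len"] = st.aln_len());
}

// symbol of `read` aligned on top of reference position pos0 (0-based);
// "-" if the read has a deletion there
// [[Rcpp::export(name = ".cpp_aligned_base_at")]]
std::string cpp_aligned_base_at(std::string read, std::string ref, int pos0) {
  std::string ar, af;
  unit_align(read, ref, ar, af);
  int rp = -1;
  for (size_t col = 0; col < af.size(); ++col) {
    if (af[col] != '-') {
      ++rp;
      if (rp == pos0) return std::string(1, ar[col]);
    }
  }
  return "";
}

// [[Rcpp::export(name = ".cpp_hc")]]
std::string cpp_hc(std::string s) { return hc_compress(s); }

// [[Rcpp::export(name = ".cpp_minimizers")]]
List cpp_minimizers(std::string seq, int k, int w) {
  std::vector<int> pos;
  minimizers_of(seq, k, w, pos);
  CharacterVector kmers(pos.size());
  IntegerVector p(pos.size());
  for (size_t i = 0; i < pos.size(); ++i) {
    kmers[i] = seq.substr(pos[i], k);
    p[i] = pos[i];
  }
  return List::create(_["kmer"] = kmers, _["pos"] = p);
}

// [[Rcpp::export(name = ".cpp_wis")]]
IntegerVector cpp_wis(IntegerVector begin, IntegerVector end,
                      NumericVector weight) {
  std::vector<int> b(begin.begin(), begin.end());
  std::vector<int> e(end.begin(), end.end());
  std::vector<double> w(weight.begin(), weight.end());
  std::vector<int> sel = wis_solve(b, e, w);
  IntegerVector out(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) out[i] = sel[i] + 1;  // 1-based
  return out;
}

// [[Rcpp::export(name = ".cpp_poa_consensus")]]
std::string cpp_poa_consensus(std::vector<std::string> segs) {
  return poa_consensus(segs);
}

// [[Rcpp::export(name = ".cpp_build_matrix")]]
List cpp_build_matrix(std::vector<std::string> segs, std::string consensus) {
  MsaMatrix m = build_msa(segs, consensus);
  CharacterVector rows(m.rows.size());
  for (size_t i = 0; i < m.rows.size(); ++i) rows[i] = m.rows[i];
  return List::create(_["rows"] = rows,
                      _["consensus_row"] = m.consensus_row);
}

// [[Rcpp::export(name = ".cpp_trusted_sets")]]
List cpp_trusted_sets(std::vector<std::string> rows,
                      std::string consensus_row, int k, double T) {
  MsaMatrix m;
  m.rows = rows;
  m.consensus_row = consensus_row;
  std::vector<std::vector<Trusted>> tr = trusted_sets_of(m, k, T);
  List out(tr.size());
  for (size_t j = 0; j < tr.size(); ++j) {
    CharacterVector ctx(tr[j].size()), var(tr[j].size());
    IntegerVector cnt(tr[j].size());
    LogicalVector cons(tr[j].size());
    for (size_t t = 0; t < tr[j].size(); ++t) {
      ctx[t] = tr[j][t].context;
      var[t] = std::string(1, tr[j][t].variant);
      cnt[t] = tr[j][t].count;
      cons[t] = tr[j][t].is_consensus;
    }
    out[j] = DataFrame::create(_["context"] = ctx, _["variant"] = var,
                               _["count"] = cnt, _["consensus"] = cons,
                               _["stringsAsFactors"] = false);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_correct_rows")]]
CharacterVector cpp_correct_rows(std::vector<std::string> rows,
                                 std::string consensus_row, int k, double T,
                                 IntegerVector which_rows) {
  MsaMatrix m;
  m.rows = rows;
  m.consensus_row = consensus_row;
  std::vector<std::vector<Trusted>> tr = trusted_sets_of(m, k, T);
  CharacterVector out(which_rows.size());
  for (int i = 0; i < which_rows.size(); ++i) {
    std::string syms = correct_row_syms(rows[which_rows[i] - 1], tr, k);
    std::string res;
    for (char c : syms) if (c != '-') res.push_back(c);
    out[i] = res;
  }
  return out;
}
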