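#include <Rcpp.h>
using namespace Rcpp;

namespace {
inline int base_index(char b) {
  switch (b) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}
}

// Accumulate alignment columns into error-profile counters.
// reads are already orientation-resolved (reverse-complemented for '-' hits),
// so every alignment is walked in reference coordinates. Read 'N' columns
// count as aligned matches but are excluded from substitution statistics and
// from the substitution matrix; reference positions under the exclusion mask
// contribute to subst_bases but never to the matrix or per-base totals.
// [[Rcpp::export(name = ".tally_cpp")]]
List tally_cpp(CharacterVector ops, IntegerVector ref_idx, IntegerVector ref_start,
               IntegerVector read_start, CharacterVector oriented_reads,
               CharacterVector refs, List excluded_masks) {
  int namp = refs.size();
  std::vector<std::string> refv(namp);
  std::vector<std::vector<int>> excl(namp);
  for (int k = 0; k < namp; ++k) {
    refv[k] = as<std::string>(refs[k]);
    LogicalVector m = excluded_masks[k];
    excl[k].assign(m.begin(), m.end());
  }
  // per-amplicon counters
  IntegerVector aligned_reads(namp), del_b(namp);
  NumericVector aligned_b(namp), subst_b(namp), ins_b(namp);
  IntegerMatrix mat(4, 4);
  NumericVector totals(4);
  int n = ops.size();
  for (int r = 0; r < n; ++r) {
    int k = ref_idx[r] - 1;
    if (k < 0 || k >= namp) stop("reference index out of range");
    const std::string& ref = refv[k];
    std::string o = as<std::string>(ops[r]);
    std::string rd = as<std::string>(oriented_reads[r]);
    size_t i = (size_t)read_start[r], j = (size_t)ref_start[r];
    aligned_reads[k] += 1;
    for (char c : o) {
      if (c == 'M' || c == 'X') {
        if (j >= ref.size() || i >= rd.size())
          stop("alignment walks off the reference/read (read %d)", r + 1);
        char rb = ref[j], qb = rd[i];
        aligned_b[k] += 1;
        if (qb != 'N') {
          int ri = base_index(rb), qi = base_index(qb);
          bool ex = excl[k][j] != 0;
          if (qb != rb) {
            subst_b[k] += 1;
            if (!ex && ri >= 0 && qi >= 0) mat(ri, qi) += 1;
          }
          if (!ex && ri >= 0) totals[ri] += 1;
        }
        ++i; ++j;
      } else if (c == 'I') {
        ins_b[k] += 1; ++i;
      } else if (c == 'D') {
        del_b[k] += 1; ++j;
      } else {
        stop("unknown op '%c'", c);
      }
    }
  }
  return List::create(_["aligned_reads"] = aligned_reads,
                      _["aligned_bases"] = aligned_b,
                      _["subst_bases"] = subst_b,
                      _["ins_bases"] = ins_b,
                      _["del_bases"] = del_b,
                      _["subst_matrix_counts"] = mat,
                      _["per_base_totals"] = totals);
}
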