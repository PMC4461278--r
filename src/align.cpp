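#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh recurrences.
// Gap convention: a gap of length k costs gap_open + k * gap_extend, so a
// single-base gap scores gap_open + gap_extend. 'N' mismatches every base.

namespace {

inline int subst_score(char a, char b, int ma, int mi) {
  if (a == 'N' || b == 'N') return mi;
  return (a == b) ? ma : mi;
}

const int NEG = -1000000000;

// Score-only pass with rolling rows. Ties on the max cell keep the later
// cell in scan order (longer alignments win), matching the traceback pass.
int sw_score_only(const char* read, int n, const char* ref, int m,
                  int ma, int mi, int go, int ge) {
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0;       // H[i-1][j-1]
    int F = NEG;        // deletion state along the row
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[j] + go + ge, E[j] + ge);       // gap in ref (I)
      int f = std::max(H[j - 1] + go + ge, F + ge);      // gap in read (D)
      int h = diag + subst_score(read[i - 1], ref[j - 1], ma, mi);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      E[j] = e;
      F = f;
      if (h >= best) best = h;
    }
  }
  return best;
}

struct Aln {
  int score, read_start, read_end, ref_start, ref_end; // 0-based half-open
  std::string ops;                                     // over {M,X,I,D}
};

// Full traceback pass (only run on the winning reference/strand).
Aln sw_traceback(const char* read, int n, const char* ref, int m,
                 int ma, int mi, int go, int ge) {
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  // pointers: for H: 0=stop,1=diag,2=from E,3=from F; for E/F: whether opened from H
  std::vector<unsigned char> PH((n + 1) * W, 0), PE((n + 1) * W, 0), PF((n + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * W + j;
      int eo = H[idx - W] + go + ge, ee = E[idx - W] + ge;
      int e = std::max(eo, ee);
      PE[idx] = (eo >= ee) ? 1 : 0;
      int fo = H[idx - 1] + go + ge, fe = F[idx - 1] + ge;
      int f = std::max(fo, fe);
      PF[idx] = (fo >= fe) ? 1 : 0;
      int d = H[idx - W - 1] + subst_score(read[i - 1], ref[j - 1], ma, mi);
      int h = d;
      unsigned char p = 1;
      if (e > h) { h = e; p = 2; }
      if (f > h) { h = f; p = 3; }
      if (h <= 0) { h = 0; p = 0; }
      H[idx] = h; E[idx] = e; F[idx] = f; PH[idx] = p;
      if (h >= best) { best = h; bi = i; bj = j; }
    }
  }
  Aln out;
  out.score = best;
  out.read_end = bi;
  out.ref_end = bj;
  std::string rev;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    int idx = i * W + j;
    if (state == 0) {
      unsigned char p = PH[idx];
      if (p == 0 || H[idx] == 0) break;
      if (p == 1) {
        char rb = read[i - 1], cb = ref[j - 1];
        rev.push_back((rb == cb || rb == 'N' || cb == 'N') ? 'M' : 'X');
        --i; --j;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      rev.push_back('I');
      if (PE[idx]) state = 0;
      --i;
    } else {
      rev.push_back('D');
      if (PF[idx]) state = 0;
      --j;
    }
  }
  out.read_start = i;
  out.ref_start = j;
  out.ops.assign(rev.rbegin(), rev.rend());
  return out;
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

} // namespace

// [[Rcpp::export(name = ".sw_pair_cpp")]]
List sw_pair_cpp(std::string read, std::string ref,
                 int match, int mismatch, int gap_open, int gap_extend) {
  Aln a = sw_traceback(read.c_str(), read.size(), ref.c_str(), ref.size(),
                       match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = a.score, _["ops"] = a.ops,
                      _["read_start"] = a.read_start, _["read_end"] = a.read_end,
                      _["ref_start"] = a.ref_start, _["ref_end"] = a.ref_end);
}

// Align each read against every reference in both orientations; report the
// best per read. Ties: higher score, then panel order, then '+' strand.
// For '-' strand hits all coordinates and ops refer to the reverse
// complement of the read (i.e. reference coordinates).
// [[Rcpp::export(name = ".align_batch_cpp")]]
List align_batch_cpp(CharacterVector reads, CharacterVector refs,
                     int match, int mismatch, int gap_open, int gap_extend,
                     double min_score_fraction) {
  int nr = reads.size(), nf = refs.size();
  std::vector<std::string> refv(nf);
  for (int k = 0; k < nf; ++k) refv[k] = as<std::string>(refs[k]);
  IntegerVector ref_idx(nr), score(nr), ref_start(nr), ref_end(nr),
      read_start(nr), read_end(nr);
  CharacterVector strand(nr), ops(nr);
  LogicalVector aligned(nr);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    std::string rc = revcomp_str(rd);
    int best = -1, bk = -1, bs = 0; // bs: 0 = '+', 1 = '-'
    for (int k = 0; k < nf; ++k) {
      for (int s = 0; s < 2; ++s) {
        const std::string& q = s ? rc : rd;
        int sc = sw_score_only(q.c_str(), q.size(), refv[k].c_str(), refv[k].size(),
                               match, mismatch, gap_open, gap_extend);
        if (sc > best) { best = sc; bk = k; bs = s; }
      }
    }
    const std::string& q = bs ? rc : rd;
    Aln a = sw_traceback(q.c_str(), q.size(), refv[bk].c_str(), refv[bk].size(),
                         match, mismatch, gap_open, gap_extend);
    ref_idx[r] = bk + 1;
    strand[r] = bs ? "-" : "+";
    score[r] = a.score;
    ref_start[r] = a.ref_start;
    ref_end[r] = a.ref_end;
    read_start[r] = a.read_start;
    read_end[r] = a.read_end;
    ops[r] = a.ops;
    aligned[r] = a.score >= min_score_fraction * match * (double)rd.size() &&
                 rd.size() > 0;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["ref_idx"] = ref_idx, _["strand"] = strand,
                      _["score"] = score, _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end, _["read_start"] = read_start,
                      _["read_end"] = read_end, _["ops"] = ops,
                      _["aligned"] = aligned);
}
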