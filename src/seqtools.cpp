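#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int k = 0; k < n; ++k) {
    if (CharacterVector::is_na(x[k])) { out[k] = NA_STRING; continue; }
    std::string s = as<std::string>(x[k]);
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'C': c = 'G'; break;
        case 'G': c = 'C'; break; case 'T': c = 'A'; break;
        case 'N': break;
        default: stop("revcomp: unexpected character '%c'", c);
      }
    }
    out[k] = r;
  }
  return out;
}

// Replace bases whose Phred+33 quality falls below `threshold` with 'N'.
// [[Rcpp::export(name = ".mask_bases_cpp")]]
CharacterVector mask_bases_cpp(CharacterVector bases, CharacterVector quals,
                               int threshold) {
  int n = bases.size();
  CharacterVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string b = as<std::string>(bases[k]);
    std::string q = as<std::string>(quals[k]);
    if (b.size() != q.size()) stop("bases/quals length mismatch at record %d", k + 1);
    for (size_t i = 0; i < b.size(); ++i)
      if ((int)q[i] - 33 < threshold) b[i] = 'N';
    out[k] = b;
  }
  return out;
}

// [[Rcpp::export(name = ".mean_phred_cpp")]]
NumericVector mean_phred_cpp(CharacterVector quals) {
  int n = quals.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string q = as<std::string>(quals[k]);
    if (q.empty()) { out[k] = NA_REAL; continue; }
    double s = 0;
    for (char c : q) s += (int)c - 33;
    out[k] = s / q.size();
  }
  return out;
}

// [[Rcpp::export(name = ".count_char_cpp")]]
IntegerVector count_char_cpp(CharacterVector x, char what) {
  int n = x.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string s = as<std::string>(x[k]);
    out[k] = std::count(s.begin(), s.end(), what);
  }
  return out;
}

// Hamming distance between `pattern` and the window of each string starting
// at 0-based `offset`; -1 when the string is too short for the window.
// [[Rcpp::export(name = ".hamming_window_cpp")]]
IntegerVector hamming_window_cpp(CharacterVector x, std::string pattern, int offset) {
  int n = x.size(), m = pattern.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string s = as<std::string>(x[k]);
    if ((int)s.size() < offset + m) { out[k] = -1; continue; }
    int d = 0;
    for (int i = 0; i < m; ++i) d += (s[offset + i] != pattern[i]);
    out[k] = d;
  }
  return out;
}

// Best approximate occurrence of `pattern` in each string at or after
// 0-based `from`: returns the 1-based start of the lowest-mismatch window
// (earliest on ties) or NA when the best exceeds `max_mm`.
// [[Rcpp::export(name = ".find_approx_cpp")]]
IntegerVector find_approx_cpp(CharacterVector x, std::string pattern,
                              int max_mm, int from) {
  int n = x.size(), m = pattern.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string s = as<std::string>(x[k]);
    int bestd = max_mm + 1, bestp = -1;
    for (int p = from; p + m <= (int)s.size(); ++p) {
      int d = 0;
      for (int i = 0; i < m && d < bestd; ++i) d += (s[p + i] != pattern[i]);
      if (d < bestd) { bestd = d; bestp = p; }
      if (bestd == 0) break;
    }
    out[k] = (bestp < 0) ? NA_INTEGER : bestp + 1;
  }
  return out;
}
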