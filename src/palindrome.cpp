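#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Maximal approximate palindrome in an integer-coded sequence
// (A=0, C=1, G=2, T=3, N=-1; complement of base c is 3-c).
//
// A configuration is a left arm ending at position p (1-based, arm =
// seq[p-s+1 .. p]), a loop of length q-p >= 0, and a right arm starting at
// q+1. The right arm is aligned against the reverse complement of the left
// arm by edit distance (mismatches + indels). Stem length s is the left arm
// length; a stem is feasible when the minimal edit count over right-arm
// lengths is <= floor(max_error_rate * s). Returns the configuration with
// maximal feasible s, ties broken by fewer edits, then leftmost (p, then q).
//
// [[Rcpp::export]]
List max_approx_palindrome_cpp(IntegerVector code, int min_stem,
                               double max_error_rate) {
  int n = code.size();
  int best_s = 0, best_e = n + 1, bp = -1, bq = -1, bt = -1;
  // arms longer than this can never satisfy the error bound
  int s_cap = (int)std::floor(n / (2.0 - max_error_rate)) + 1;
  std::vector<int> prev(n + 1), curr(n + 1);
  for (int p = 1; p <= n; ++p) {
    if (p < min_stem) continue;
    for (int q = p; q <= n; ++q) {
      int maxs = p < s_cap ? p : s_cap;
      int maxt = n - q;
      for (int t = 0; t <= maxt; ++t) prev[t] = t;
      for (int s = 1; s <= maxs; ++s) {
        int a = code[p - s];  // complement compared below
        curr[0] = s;
        int rowmin = curr[0], argt = 0;
        for (int t = 1; t <= maxt; ++t) {
          int b = code[q + t - 1];
          int sub = prev[t - 1] + ((a >= 0 && b >= 0 && b == 3 - a) ? 0 : 1);
          int del = prev[t] + 1;
          int ins = curr[t - 1] + 1;
          int v = sub < del ? sub : del;
          if (ins < v) v = ins;
          curr[t] = v;
          if (v < rowmin) { rowmin = v; argt = t; }
        }
        if (s >= min_stem) {
          int allowed = (int)std::floor(max_error_rate * s + 1e-9);
          if (rowmin <= allowed &&
              (s > best_s || (s == best_s && rowmin < best_e))) {
            best_s = s; best_e = rowmin; bp = p; bq = q; bt = argt;
          }
        }
        std::swap(prev, curr);
      }
    }
  }
  if (best_s == 0) return List::create(Named("stem") = 0);
  return List::create(
    Named("stem") = best_s, Named("edits") = best_e,
    Named("left_start") = bp - best_s + 1, Named("left_end") = bp,
    Named("right_start") = bq + 1, Named("right_end") = bq + bt,
    Named("loop") = bq - bp);
}

// Stem scores for many sequences; sequences without a feasible stem score
// min_stem - 1 so paired comparisons stay defined.
// [[Rcpp::export]]
NumericVector palindrome_stems_cpp(List codes, int min_stem,
                                   double max_error_rate) {
  int m = codes.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    IntegerVector code = codes[i];
    List hit = max_approx_palindrome_cpp(code, min_stem, max_error_rate);
    int s = as<int>(hit["stem"]);
    out[i] = s > 0 ? s : min_stem - 1;
  }
  return out;
}
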