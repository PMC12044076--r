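#include <Rcpp.h>
using namespace Rcpp;

// Sample-entropy match counts under the Chebyshev (maximum) norm.
// Returns B = #template pairs (i < j) matching at length m and
// A = #pairs still matching at length m + 1; self-matches excluded
// by construction (i < j).
// Scans each lag d once, tracking the run length of consecutive
// within-tolerance sample pairs along the diagonal, so every sample pair
// is compared exactly once (a length-m template match ending at t
// corresponds to a run of >= m matches).
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double tol) {
  const int n = x.size();
  const int last_i = n - m - 1;  // last template start (0-based)
  double A = 0.0, B = 0.0;
  for (int d = 1; d <= last_i; ++d) {
    int run = 0;
    const int tmax = n - 1 - d;
    for (int t = 0; t <= tmax; ++t) {
      if (std::fabs(x[t] - x[t + d]) <= tol) ++run; else run = 0;
      if (run >= m && t - m + 1 <= last_i - d) B += 1.0;
      if (run >= m + 1 && t - m <= last_i - d) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// LZ76 phrase count of a 0/1 integer sequence (Lempel & Ziv 1976
// exhaustive-history parsing, Kaspar & Schuster formulation).
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1;       // the first symbol is always its own phrase
  int i = 1;       // start of current phrase (history = s[0..i-1] + prefix)
  int k = 1;       // current extension length
  int kmax = 1;    // longest reproducible extension so far
  int j = 0;       // candidate match start within history
  while (true) {
    if (s[i + k - 1] == s[j + k - 1]) {
      ++k;
      if (i + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++j;
      if (j == i) {          // no history position reproduces the extension
        ++c;
        i += kmax;
        if (i + 1 > n) break;
        j = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
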