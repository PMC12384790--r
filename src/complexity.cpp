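#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv (1976) exhaustive-history phrase count over an arbitrary
// integer alphabet, via the Kaspar-Schuster scanning algorithm.
// Each phrase is the shortest prefix of the unparsed remainder that cannot
// be copied (with overlap allowed) from the already-seen history.
// [[Rcpp::export]]
int lz76_phrase_count(const IntegerVector& s) {
  const int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1;    // phrase counter; first symbol is always a phrase
  int l = 1;    // start (0-based) of the current phrase
  int i = 0;    // candidate copy source within the history
  int k = 1;    // current match length
  int kmax = 1; // longest match over sources tried so far
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) { // no source reproduces a longer prefix: phrase ends
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Template-match counts for sample entropy: number of ordered pairs
// (i, j), i < j, whose m-point (and (m+1)-point) subsequences stay within
// Chebyshev distance r. Self-matches are excluded by construction.
// Returns c(B = m-length matches, A = (m+1)-length matches).
// [[Rcpp::export]]
NumericVector sampen_match_counts(const NumericVector& x, int m, double r) {
  const int n = x.size();
  double A = 0.0, B = 0.0;
  // templates of length m exist at i = 0..n-m; length m+1 at i = 0..n-m-1
  for (int i = 0; i + m < n; ++i) {
    for (int j = i + 1; j + m < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::abs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        double dm = std::abs(x[i + m] - x[j + m]);
        if (std::max(d, dm) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["B"] = B, _["A"] = A);
}
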