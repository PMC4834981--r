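#include <Rcpp.h>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

// Pair counting for sample entropy.
//
// Templates are the N - m vectors of m consecutive points, start index
// i in [0, N - m) (0-based), so every template considered has a length
// (m + 1) extension.  B counts unordered pairs i < j whose length-m
// templates match (Chebyshev distance strictly < r); A counts those same
// pairs whose length-(m + 1) extensions also match.
//
// The scan sorts template start indices by the first coordinate and walks
// a two-pointer window: a pair can only match if its first coordinates
// differ by less than r, which prunes the quadratic pair set to the
// near-diagonal band.  Counts are accumulated in long long (pair counts
// reach ~5e9 for N = 1e5) and returned as doubles.

// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates (all have extensions)
  if (nt < 2) return NumericVector::create(_["A"] = 0.0, _["B"] = 0.0);

  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  const double *xp = REAL(x);
  std::sort(ord.begin(), ord.end(),
            [xp](int a, int b) { return xp[a] < xp[b]; });

  long long A = 0, B = 0;
  for (int a = 0; a < nt - 1; ++a) {
    const int i = ord[a];
    const double x0 = xp[i];
    for (int b = a + 1; b < nt; ++b) {
      const int j = ord[b];
      if (xp[j] - x0 >= r) break;  // sorted: no later b can match
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::abs(xp[i + k] - xp[j + k]) >= r) { match = false; break; }
      }
      if (!match) continue;
      ++B;
      if (std::abs(xp[i + m] - xp[j + m]) < r) ++A;
    }
  }
  return NumericVector::create(_["A"] = (double)A, _["B"] = (double)B);
}
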