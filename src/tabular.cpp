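// Dense additive relationship matrix by the tabular method. Codes are
// 1-based pedigree codes with 0 = unknown parent; parents precede offspring.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".tabular_A_cpp")]]
NumericMatrix tabular_A_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  double *a = A.begin();
  for (int j = 0; j < n; ++j) {
    const int s = sire[j] - 1, d = dam[j] - 1;   // -1 = unknown
    double *colj = a + (size_t)n * j;
    if (s >= 0 && d >= 0) {
      const double *cs = a + (size_t)n * s;
      const double *cd = a + (size_t)n * d;
      for (int i = 0; i < j; ++i) colj[i] = 0.5 * (cs[i] + cd[i]);
      colj[j] = 1.0 + 0.5 * cs[d];
    } else if (s >= 0) {
      const double *cs = a + (size_t)n * s;
      for (int i = 0; i < j; ++i) colj[i] = 0.5 * cs[i];
      colj[j] = 1.0;
    } else if (d >= 0) {
      const double *cd = a + (size_t)n * d;
      for (int i = 0; i < j; ++i) colj[i] = 0.5 * cd[i];
      colj[j] = 1.0;
    } else {
      colj[j] = 1.0;
    }
    // mirror into row j (column-major: strided writes)
    for (int i = 0; i < j; ++i) a[(size_t)n * i + j] = colj[i];
  }
  return A;
}

// Inbreeding coefficients only: same recursion, but row i of A is dropped
// once every later animal's column has consumed it. To stay simple and
// exact we keep the full matrix for moderate n; this entry point exists so
// F can be computed without returning the n x n matrix to R.
// [[Rcpp::export(name = ".tabular_F_cpp")]]
NumericVector tabular_F_cpp(IntegerVector sire, IntegerVector dam) {
  NumericMatrix A = tabular_A_cpp(sire, dam);
  const int n = sire.size();
  NumericVector f(n);
  for (int j = 0; j < n; ++j) f[j] = A(j, j) - 1.0;
  return f;
}
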