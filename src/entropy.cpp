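#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev (max-component) template matching for ApEn / SampEn.
// Both statistics embed x into overlapping vectors of length m and count
// pairs whose component-wise distance never exceeds r.

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for embedding length m");
  if (r <= 0) stop("tolerance r must be positive");

  double phi[2]; // phi[0] for m, phi[1] for m+1
  for (int k = 0; k < 2; ++k) {
    int mm = m + k;
    int nvec = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < nvec; ++i) {
      int cnt = 0;
      for (int j = 0; j < nvec; ++j) { // self-match included (j == i counts)
        double d = 0.0;
        for (int l = 0; l < mm; ++l) {
          double dl = std::fabs(x[i + l] - x[j + l]);
          if (dl > d) d = dl;
          if (d > r) break;
        }
        if (d <= r) ++cnt;
      }
      acc += std::log((double)cnt / nvec);
    }
    phi[k] = acc / nvec;
  }
  return phi[0] - phi[1];
}

// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for embedding length m");
  if (r <= 0) stop("tolerance r must be positive");

  // count over the N - m templates so every m-template has an (m+1) extension
  int nvec = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nvec - 1; ++i) {
    for (int j = i + 1; j < nvec; ++j) { // i < j: self-matches excluded
      double d = 0.0;
      for (int l = 0; l < m; ++l) {
        double dl = std::fabs(x[i + l] - x[j + l]);
        if (dl > d) d = dl;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  if (B == 0.0 || A == 0.0) return NA_REAL; // undefined, caller logs
  return -std::log(A / B);
}
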