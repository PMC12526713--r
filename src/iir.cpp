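#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, zero initial conditions.
// Coefficients come from signal::butter (a[0] normalised to 1 upstream).

static void filt_inplace(const std::vector<double>& bb, const std::vector<double>& aa,
                         int nz, double* x, int n, int step) {
  std::vector<double> z(nz, 0.0);
  for (int t = 0; t < n; ++t) {
    double xn = x[t * step];
    double yn = bb[0] * xn + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xn + z[k + 1] - aa[k + 1] * yn;
    if (nz > 0) z[nz - 1] = bb[nz] * xn - aa[nz] * yn;
    x[t * step] = yn;
  }
}

// forward-backward (zero-phase) filtering, zero initial conditions;
// the caller supplies adequate padding
// [[Rcpp::export]]
NumericVector filtfilt_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y = clone(x);
  filt_inplace(bb, aa, nz, y.begin(), n, 1);
  filt_inplace(bb, aa, nz, y.begin() + (n - 1), n, -1);
  return y;
}

// centred FIR smoothing with reflected edges (odd-length kernel)
// [[Rcpp::export]]
NumericVector fir_smooth_cpp(NumericVector x, NumericVector w) {
  int n = x.size(), k = w.size(), h = k / 2;
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double acc = 0.0;
    for (int j = -h; j <= h; ++j) {
      int i = t + j;
      if (i < 0) i = -i;                    // reflect
      if (i >= n) i = 2 * (n - 1) - i;
      acc += w[j + h] * x[i];
    }
    y[t] = acc;
  }
  return y;
}

// remove best-fit straight line
// [[Rcpp::export]]
NumericVector detrend_cpp(NumericVector x) {
  int n = x.size();
  double mx = 0.0, mt = (n + 1) / 2.0, stx = 0.0, stt = 0.0;
  for (int i = 0; i < n; ++i) mx += x[i];
  mx /= n;
  for (int i = 0; i < n; ++i) {
    double t = (i + 1) - mt;
    stx += t * (x[i] - mx);
    stt += t * t;
  }
  double slope = stx / stt;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) y[i] = x[i] - mx - ((i + 1) - mt) * slope;
  return y;
}

// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xn = x[t];
    double yn = bb[0] * xn + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xn + z[k + 1] - aa[k + 1] * yn;
    if (nz > 0) z[nz - 1] = bb[nz] * xn - aa[nz] * yn;
    y[t] = yn;
  }
  return y;
}
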