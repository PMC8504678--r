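#include <Rcpp.h>
using namespace Rcpp;

// one-pass direct-form II transposed IIR along a vector
static void iir(const std::vector<double>& b, const std::vector<double>& a,
                std::vector<double>& x) {
  const int nc = std::max(b.size(), a.size());
  const int nz = nc - 1, n = x.size();
  std::vector<double> bb(nc, 0.0), aa(nc, 0.0);
  for (size_t k = 0; k < b.size(); ++k) bb[k] = b[k];
  for (size_t k = 0; k < a.size(); ++k) aa[k] = a[k];
  if (nc == 5) { // unrolled 4th-order fast path
    double z0 = 0, z1 = 0, z2 = 0, z3 = 0;
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4];
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi - a1 * yi + z1;
      z1 = b2 * xi - a2 * yi + z2;
      z2 = b3 * xi - a3 * yi + z3;
      z3 = b4 * xi - a4 * yi;
      x[i] = yi;
    }
    return;
  }
  std::vector<double> z(nc, 0.0); // z[nz] stays 0
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nz; ++k)
      z[k] = bb[k + 1] * xi - aa[k + 1] * yi + z[k + 1];
    x[i] = yi;
  }
}

// [[Rcpp::export(name = ".filtfilt_mat")]]
NumericMatrix filtfilt_mat(NumericMatrix X, NumericVector b, NumericVector a) {
  const int n = X.nrow(), m = X.ncol();
  const std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  const int pad = 3 * std::max(bb.size(), aa.size());
  if (n <= pad + 1) stop("series too short for filtfilt padding");
  NumericMatrix out(n, m);
  std::vector<double> w(n + 2 * pad);
  for (int j = 0; j < m; ++j) {
    // odd reflection padding at both ends
    for (int i = 0; i < pad; ++i)
      w[i] = 2.0 * X(0, j) - X(pad - i, j);
    for (int i = 0; i < n; ++i) w[pad + i] = X(i, j);
    for (int i = 0; i < pad; ++i)
      w[pad + n + i] = 2.0 * X(n - 1, j) - X(n - 2 - i, j);
    iir(bb, aa, w);
    std::reverse(w.begin(), w.end());
    iir(bb, aa, w);
    std::reverse(w.begin(), w.end());
    for (int i = 0; i < n; ++i) out(i, j) = w[pad + i];
  }
  return out;
}

// per-row max, min and variance of a matrix (rows = trial-channel series)
// [[Rcpp::export(name = ".row_stats")]]
NumericMatrix row_stats(NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double mx = X(i, 0), mn = X(i, 0), s = 0.0, s2 = 0.0;
    for (int j = 0; j < m; ++j) {
      const double v = X(i, j);
      if (v > mx) mx = v;
      if (v < mn) mn = v;
      s += v; s2 += v * v;
    }
    out(i, 0) = mx;
    out(i, 1) = mn;
    out(i, 2) = s2 / m - (s / m) * (s / m);
  }
  return out;
}
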