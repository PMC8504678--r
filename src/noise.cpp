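#include <Rcpp.h>
using namespace Rcpp;

// 1/f-shaped ("pink") Gaussian noise via the classic 6-pole parallel
// one-pole approximation (Kellet's refined filter): each state is an AR(1)
// driven by the shared white input. States are initialized from their exact
// joint stationary distribution, so every column is a stationary series
// with no warm-up, and the output is scaled by the analytic stationary SD.
static const double P[6] = {0.99886, 0.99332, 0.96900, 0.86650, 0.55000,
                            -0.7616};
static const double G[6] = {0.0555179, 0.0750759, 0.1538520, 0.3104856,
                            0.5329522, -0.0168980};
static const double A0 = 0.5362;    // direct feedthrough of the current input
static const double C6 = 0.115926;  // one-sample-delayed feedthrough

// [[Rcpp::export(name = ".shaped_noise_cpp")]]
NumericMatrix shaped_noise_cpp(int n, int m, double w_pink) {
  NumericMatrix out(n, m);
  RNGScope scope;
  const double ww = std::sqrt(1.0 - w_pink), wp = std::sqrt(w_pink);
  if (w_pink <= 0.0) {
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i) out(i, j) = norm_rand();
    return out;
  }
  // joint stationary covariance of (b0..b5, w_prev)
  double S[7][7];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) S[i][j] = G[i] * G[j] / (1.0 - P[i] * P[j]);
  for (int i = 0; i < 6; ++i) { S[i][6] = G[i]; S[6][i] = G[i]; }
  S[6][6] = 1.0;
  // Cholesky S = L L^T
  double L[7][7] = {{0}};
  for (int i = 0; i < 7; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = S[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      L[i][j] = (i == j) ? std::sqrt(s) : s / L[j][j];
    }
  }
  // stationary output variance: pink = sum_k P_k b_k^- + A w_t + C6 w_prev
  // with A = sum_k G_k + A0 and cov(b_k^-, w_prev) = G_k
  double Asum = A0, pg = 0.0, vb = 0.0;
  for (int k = 0; k < 6; ++k) {
    Asum += G[k];
    pg += P[k] * G[k];
    for (int l = 0; l < 6; ++l) vb += P[k] * P[l] * S[k][l];
  }
  const double sd = std::sqrt(vb + Asum * Asum + C6 * C6 + 2.0 * C6 * pg);

  double b[6], z[7];
  for (int j = 0; j < m; ++j) {
    for (int k = 0; k < 7; ++k) z[k] = norm_rand();
    double wprev = 0.0;
    for (int i = 0; i < 6; ++i) {
      b[i] = 0.0;
      for (int k = 0; k <= i; ++k) b[i] += L[i][k] * z[k];
    }
    for (int k = 0; k < 7; ++k) wprev += L[6][k] * z[k];
    double b6 = C6 * wprev;
    for (int i = 0; i < n; ++i) {
      const double w = norm_rand();
      double y = A0 * w + b6;
      for (int k = 0; k < 6; ++k) {
        b[k] = P[k] * b[k] + G[k] * w;
        y += b[k];
      }
      b6 = C6 * w;
      out(i, j) = ww * norm_rand() + wp * y / sd;
    }
  }
  return out;
}
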