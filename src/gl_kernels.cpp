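#include <Rcpp.h>
using namespace Rcpp;

// Grünwald-Letnikov weights psi(alpha, j), j = 0..J, by the stable recursion
// psi(alpha, j) = psi(alpha, j-1) * (j - 1 - alpha) / j, psi(alpha, 0) = 1.
// Equals Gamma(j - alpha) / (Gamma(-alpha) * Gamma(j + 1)) for all real alpha.
// [[Rcpp::export(name = ".gl_coeffs_cpp")]]
NumericVector gl_coeffs_cpp(double alpha, int J) {
  NumericVector psi(J + 1);
  psi[0] = 1.0;
  for (int j = 1; j <= J; ++j)
    psi[j] = psi[j - 1] * ((double)j - 1.0 - alpha) / (double)j;
  return psi;
}

// Truncated fractional difference (Delta^alpha x)[k] = sum_{j=0}^{min(k,J)}
// psi(alpha, j) x[k-j]; direct convolution, 0-based k with no pre-sample
// history (x[-1] absent, so out[0] = x[0]).
// [[Rcpp::export(name = ".frac_diff_cpp")]]
NumericVector frac_diff_cpp(NumericVector x, NumericVector psi) {
  int n = x.size(), J = psi.size() - 1;
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    int m = k < J ? k : J;
    double acc = 0.0;
    for (int j = 0; j <= m; ++j) acc += psi[j] * x[k - j];
    out[k] = acc;
  }
  return out;
}

// Simulate the fractional coupled system
//   Delta^alpha_i x_i[k+1] = (A x[k] + B u[k] + eps[k+1])_i
// i.e. x[k+1] = A x[k] + B u[k] + eps[k+1] - sum_{j=1}^{k+1} psi(alpha_i, j)
// x_i[k+1-j], with full Grünwald-Letnikov memory. Noise eps is pre-generated
// in R so seeding stays on the R side. x: n x T (column k = sample k).
// Returns the trajectory or stops if |x| exceeds the overflow guard.
// [[Rcpp::export(name = ".gl_simulate_cpp")]]
NumericMatrix gl_simulate_cpp(NumericMatrix A, NumericMatrix B,
                              NumericMatrix U, NumericVector alpha,
                              NumericMatrix eps, NumericVector x0,
                              double guard) {
  int n = A.nrow();
  int T = eps.ncol();            // total samples incl. the initial one
  int p = B.ncol();
  bool has_u = (U.nrow() > 0 && p > 0);
  // contiguous per-channel buffers: psi[i][j] and x[i][k] (the GL memory
  // sum scans both linearly, which matters at T ~ 6000)
  std::vector< std::vector<double> > psi(n, std::vector<double>(T));
  std::vector< std::vector<double> > xs(n, std::vector<double>(T));
  for (int i = 0; i < n; ++i) {
    psi[i][0] = 1.0;
    for (int j = 1; j < T; ++j)
      psi[i][j] = psi[i][j - 1] * ((double)j - 1.0 - alpha[i]) / (double)j;
    xs[i][0] = x0[i];
  }
  for (int k = 0; k + 1 < T; ++k) {
    for (int i = 0; i < n; ++i) {
      double drive = 0.0;
      for (int c = 0; c < n; ++c) drive += A(i, c) * xs[c][k];
      if (has_u)
        for (int c = 0; c < p; ++c) drive += B(i, c) * U(c, k);
      drive += eps(i, k + 1);
      double mem = 0.0;          // sum_{j=1}^{k+1} psi_i(j) x_i[k+1-j]
      const double *pp = psi[i].data();
      const double *xx = xs[i].data();
      for (int j = 1; j <= k + 1; ++j) mem += pp[j] * xx[k + 1 - j];
      double v = drive - mem;
      if (!std::isfinite(v) || std::fabs(v) > guard)
        stop("fractional system trajectory diverged at sample %d, channel %d",
             k + 2, i + 1);
      xs[i][k + 1] = v;
    }
  }
  NumericMatrix X(n, T);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < T; ++k) X(i, k) = xs[i][k];
  return X;
}

// Fractional differencing of every row of an n x T matrix with per-row
// alpha, shared truncation J; used by the coupling-matrix fit.
// [[Rcpp::export(name = ".frac_diff_rows_cpp")]]
NumericMatrix frac_diff_rows_cpp(NumericMatrix X, NumericVector alpha, int J) {
  int n = X.nrow(), T = X.ncol();
  NumericMatrix Z(n, T);
  std::vector<double> xi(T);
  for (int i = 0; i < n; ++i) {
    NumericVector psi = gl_coeffs_cpp(alpha[i], J);
    const double *pp = REAL(psi);
    for (int k = 0; k < T; ++k) xi[k] = X(i, k);
    for (int k = 0; k < T; ++k) {
      int m = k < J ? k : J;
      double acc = 0.0;
      for (int j = 0; j <= m; ++j) acc += pp[j] * xi[k - j];
      Z(i, k) = acc;
    }
  }
  return Z;
}
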