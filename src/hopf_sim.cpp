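#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the coupled Hopf normal-form model.
//
// Per region j (states x_j, y_j):
//   dx_j = [(a_j - x_j^2 - y_j^2) x_j - w_j y_j + G sum_i C[j,i] (x_i - x_j)] dt + sigma dW
//   dy_j = [(a_j - x_j^2 - y_j^2) y_j + w_j x_j + G sum_i C[j,i] (y_i - y_j)] dt + sigma dW
//
// C is oriented column -> row: C[j,i] couples region i into region j.
// Noise is drawn from R's RNG (norm_rand), so results are reproducible
// under set.seed() on the R side.
//
// Returns the x component subsampled every `subsample` steps after
// discarding `burn_steps` steps: an n_keep x n matrix.
// [[Rcpp::export]]
NumericMatrix hopf_sim_core(NumericMatrix C, NumericVector a,
                            NumericVector omega, double G, double sigma,
                            double dt, int n_keep, int subsample,
                            int burn_steps, NumericVector x0,
                            NumericVector y0) {
  const int n = C.nrow();
  if (C.ncol() != n || a.size() != n || omega.size() != n ||
      x0.size() != n || y0.size() != n)
    stop("inconsistent dimensions in hopf_sim_core");

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> rowsum(n, 0.0);
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += C(j, i);
    rowsum[j] = s;
  }

  NumericMatrix out(n_keep, n);
  const double sqdt = std::sqrt(dt);
  const long total = (long)burn_steps + (long)n_keep * subsample;
  RNGScope scope;

  int kept = 0;
  for (long step = 0; step < total; ++step) {
    // coupling input: G * (C %*% x - rowsum * x), same for y
    std::vector<double> cx(n, 0.0), cy(n, 0.0);
    for (int j = 0; j < n; ++j) {
      double sx = 0.0, sy = 0.0;
      for (int i = 0; i < n; ++i) {
        const double c = C(j, i);
        if (c != 0.0) { sx += c * x[i]; sy += c * y[i]; }
      }
      cx[j] = G * (sx - rowsum[j] * x[j]);
      cy[j] = G * (sy - rowsum[j] * y[j]);
    }
    for (int j = 0; j < n; ++j) {
      const double r2 = x[j] * x[j] + y[j] * y[j];
      const double dx = (a[j] - r2) * x[j] - omega[j] * y[j] + cx[j];
      const double dy = (a[j] - r2) * y[j] + omega[j] * x[j] + cy[j];
      x[j] += dt * dx + sigma * sqdt * norm_rand();
      y[j] += dt * dy + sigma * sqdt * norm_rand();
      if (!std::isfinite(x[j]) || std::fabs(x[j]) > 1e6)
        stop("Hopf trajectory diverged at integration step %ld (region %d)",
             step + 1, j + 1);
    }
    if (step >= burn_steps && ((step - burn_steps + 1) % subsample) == 0) {
      for (int j = 0; j < n; ++j) out(kept, j) = x[j];
      ++kept;
      if (kept == n_keep) break;
    }
  }
  return out;
}
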