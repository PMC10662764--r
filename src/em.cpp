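#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama endpoint simulation on the ring for the particle models.
//
// theta0      initial positions (radians), one particle per element
// trial_row   0-based row of `grid_rows` supplying each particle's drift
//             (ignored unless mode == 4)
// mode        0 flat, 1 cosine, 2 dual, 3 gridded (single row),
//             4 gridded per-trial rows
// par         mode 1: (A, n, off) with drift A*sin(n*(theta-off));
//             mode 2: (A1, n1, A2, n2, off)
// grid_rows   per-bin energy gradients; one row (mode 3) or one row per
//             trial (mode 4); n_bins columns spanning [-pi, pi)
// sigma       noise amplitude (rad / sqrt(s)); dt step (s)
//
// Positions are kept continuous; the gridded drift is looked up at the
// nearest 2*pi/n_bins bin (half-up, matching ring_bin()).
// [[Rcpp::export]]
NumericVector em_sim_cpp(NumericVector theta0, IntegerVector trial_row,
                         int mode, NumericVector par,
                         NumericMatrix grid_rows, double sigma,
                         double dt, int n_steps) {
  const int n = theta0.size();
  const double two_pi = 2.0 * M_PI;
  const int n_bins = grid_rows.ncol();
  const double inv_h = n_bins / two_pi;
  NumericVector th = clone(theta0);
  const double sig = sigma * std::sqrt(dt);
  RNGScope scope;
  for (int k = 0; k < n_steps; ++k) {
    for (int i = 0; i < n; ++i) {
      double x = th[i];
      double g = 0.0;
      switch (mode) {
      case 0: break;
      case 1:
        g = par[0] * std::sin(par[1] * (x - par[2]));
        break;
      case 2:
        g = par[0] * std::sin(par[1] * (x - par[4])) +
            par[2] * std::sin(par[3] * (x - par[4]));
        break;
      case 3: case 4: {
        double u = (x + M_PI) * inv_h + 0.5;
        int b = (int)std::floor(u);
        b %= n_bins;
        if (b < 0) b += n_bins;
        g = (mode == 3) ? grid_rows(0, b) : grid_rows(trial_row[i], b);
        break;
      }
      }
      x -= g * dt;
      if (sigma > 0.0) x += sig * norm_rand();
      // keep in a window where bin lookup stays exact
      if (x >= M_PI) x -= two_pi; else if (x < -M_PI) x += two_pi;
      th[i] = x;
    }
  }
  return th;
}
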