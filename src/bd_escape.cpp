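#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin escape from a radially symmetric in-plane trap.
// Potential (in kT): U = -W inside rho < a; linear ramp to 0 over
// [a, a + s]; field-free run-out over [a + s, a + s + g]; a trajectory
// escapes on first crossing of rho = a + s + g.
// Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
NumericVector bd_escape_cpp(int n_events, double W, double a, double s,
                            double g, double D, double dt, int max_steps) {
  NumericVector out(n_events);
  const double noise = std::sqrt(2.0 * D * dt);
  const double slope = W / s;          // |dU/drho| on the ramp, kT/nm
  const double ramp_top = a + s;
  const double rim = a + s + g;
  for (int ev = 0; ev < n_events; ++ev) {
    double x = 0.0, y = 0.0;
    int step = 0;
    for (; step < max_steps; ++step) {
      double rho = std::sqrt(x * x + y * y);
      double fx = 0.0, fy = 0.0;
      if (rho > a && rho < ramp_top) {
        // restoring drift on the rim: -dU/drho * unit radial * D
        double f = -slope * D * dt / rho;
        fx = f * x;
        fy = f * y;
      }
      x += fx + noise * norm_rand();
      y += fy + noise * norm_rand();
      if (x * x + y * y >= rim * rim) break;
    }
    out[ev] = (step + 1) * dt;
  }
  return out;
}
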