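#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) on the D-torus.
//
// The potential is a sum of cosine wells, term t acting on coordinate
// term_dim[t] (0-based): U_t(x) = (height/2) * (1 - cos(mult * (x - center))).
// Noise is drawn from R's RNG (norm_rand), one draw per coordinate per step in
// coordinate order, so a run split into blocks consumes the identical stream
// as a single uninterrupted run.

static inline double wrap_angle_c(double x) {
  return x - 2.0 * M_PI * std::ceil((x - M_PI) / (2.0 * M_PI));
}

// [[Rcpp::export]]
List cpp_langevin_run(NumericVector theta0, IntegerVector term_dim,
                      NumericVector height, NumericVector mult,
                      NumericVector center, NumericVector extra_force,
                      int n_steps, int save_every, double dt, double friction,
                      double kbt) {
  const int D = theta0.size();
  const int n_terms = term_dim.size();
  std::vector<double> th(theta0.begin(), theta0.end());
  const double drift = dt / friction;
  const double sigma = std::sqrt(2.0 * kbt * dt / friction);
  const int n_saved = (save_every > 0) ? n_steps / save_every : 0;
  NumericMatrix frames(std::max(n_saved, 0), D);
  std::vector<double> grad(D);

  int isave = 0;
  for (int s = 1; s <= n_steps; ++s) {
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int t = 0; t < n_terms; ++t) {
      const int d = term_dim[t];
      grad[d] += 0.5 * height[t] * mult[t] *
                 std::sin(mult[t] * (th[d] - center[t]));
    }
    for (int d = 0; d < D; ++d) {
      const double xi = norm_rand();
      th[d] = wrap_angle_c(th[d] + (-grad[d] + extra_force[d]) * drift +
                           sigma * xi);
      if (!std::isfinite(th[d]))
        stop("non-finite coordinate at step %d", s);
    }
    if (save_every > 0 && s % save_every == 0) {
      for (int d = 0; d < D; ++d) frames(isave, d) = th[d];
      ++isave;
    }
  }
  return List::create(_["frames"] = frames,
                      _["theta"] = NumericVector(th.begin(), th.end()));
}
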