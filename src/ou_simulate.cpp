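#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin dynamics of a trapped bead coupled to a driven spring.
//
// dx/dt = [ -k_trap * x + k_spring * (x_p(t) - x) ] / gamma + sqrt(2 kBT / gamma) xi(t)
// with x_p(t) = A sin(2 pi f t). Euler-Maruyama with `substeps` sub-steps per
// output sample; uses R's RNG so results are reproducible under set.seed().
// Units: um, pN, s; kbt in pN um; gamma in pN s/um.

// [[Rcpp::export]]
NumericVector ou_simulate_cpp(int n_samples, int substeps, double dt_sub,
                              double gamma, double k_trap, double k_spring,
                              double drive_amplitude, double drive_frequency,
                              double kbt, double x0) {
  NumericVector out(n_samples);
  const double noise_sd = std::sqrt(2.0 * kbt * dt_sub / gamma);
  const double two_pi_f = 2.0 * M_PI * drive_frequency;
  double x = x0;
  double t = 0.0;
  out[0] = x;
  for (int i = 1; i < n_samples; ++i) {
    for (int s = 0; s < substeps; ++s) {
      const double xp = drive_amplitude * std::sin(two_pi_f * t);
      const double force = -k_trap * x + k_spring * (xp - x);
      x += dt_sub * force / gamma + noise_sd * norm_rand();
      t += dt_sub;
    }
    out[i] = x;
  }
  return out;
}
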