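#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the two-variable linear system
//   dv = (-beta v + alpha V) dt + sigma dB
//   dV = ( alpha v - gamma V) dt
// for one 2D trajectory. The position r is accumulated as r += v dt and
// recorded every n_sub internal steps. Burn-in steps relax (v, V) from rest
// to stationarity before recording starts; r is reset to the origin at the
// end of the burn-in. Uses R's RNG so set.seed() gives bit-identical output.
//
// Returns an (n_samples + 1) x 2 matrix of sampled positions (row 1 = origin).
// [[Rcpp::export]]
NumericMatrix gle_sim_positions(double alpha, double beta, double gamma_,
                                double sigma, double dt, int n_sub,
                                int n_samples, int burn_steps) {
  NumericMatrix out(n_samples + 1, 2);
  double vx = 0.0, vy = 0.0, Vx = 0.0, Vy = 0.0;
  double rx = 0.0, ry = 0.0;
  const double sq = sigma * std::sqrt(dt);

  for (int i = 0; i < burn_steps; ++i) {
    double nvx = vx + (-beta * vx + alpha * Vx) * dt + sq * norm_rand();
    double nVx = Vx + (alpha * vx - gamma_ * Vx) * dt;
    double nvy = vy + (-beta * vy + alpha * Vy) * dt + sq * norm_rand();
    double nVy = Vy + (alpha * vy - gamma_ * Vy) * dt;
    vx = nvx; Vx = nVx; vy = nvy; Vy = nVy;
  }

  out(0, 0) = 0.0; out(0, 1) = 0.0;
  for (int s = 0; s < n_samples; ++s) {
    for (int i = 0; i < n_sub; ++i) {
      rx += vx * dt;
      ry += vy * dt;
      double nvx = vx + (-beta * vx + alpha * Vx) * dt + sq * norm_rand();
      double nVx = Vx + (alpha * vx - gamma_ * Vx) * dt;
      double nvy = vy + (-beta * vy + alpha * Vy) * dt + sq * norm_rand();
      double nVy = Vy + (alpha * vy - gamma_ * Vy) * dt;
      vx = nvx; Vx = nVx; vy = nvy; Vy = nVy;
    }
    out(s + 1, 0) = rx;
    out(s + 1, 1) = ry;
  }
  return out;
}
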