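#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Fixed-step integration of the leaky integrate-and-fire network.
// Membrane equation (inputs expressed as voltages, R absorbed):
//   tau_m dV_i = (-V_i + mu_i(t)) dt + sigma sqrt(tau_m) dW_i
// Between synaptic events the membrane is an Ornstein-Uhlenbeck process,
// so it is propagated exactly over each step:
//   V' = mu + (V - mu) a + sqrt(sigma^2/2 (1 - a^2)) xi,  a = exp(-dt/tau_m)
// Threshold crossings are detected at step ends; discrete sampling of a
// continuous first-passage process misses within-step excursions, which
// is equivalent to raising the barrier by |zeta(1/2)|/sqrt(2*pi) times
// the local noise scale sigma*sqrt(dt/tau_m) (the discrete-monitoring
// barrier continuity correction). The detection threshold is lowered by
// that amount so measured rates are unbiased to leading order in dt.
// Synaptic pulses J_ij from spikes in step k are applied at the start of
// step k+1 (one-step bookkeeping delay <= dt). During refractoriness V is
// clamped at V_r and all input, synaptic and stochastic, is discarded.
//
// Connectivity arrives as the slots of a dgCMatrix (post x pre, CSC), so
// column j lists the targets of presynaptic neuron j.
//
// RNG is a self-contained mt19937_64 stream seeded explicitly: the same
// quenched network can be re-simulated with fresh, reproducible noise
// without touching R's global RNG.
// [[Rcpp::export]]
List lif_integrate_cpp(NumericVector thresholds,
                       LogicalVector is_exc,
                       IntegerVector w_p, IntegerVector w_i, NumericVector w_x,
                       NumericVector v0,
                       double mu, double mu0, double sigma,
                       double s0, double f_s,
                       double dt, double duration,
                       double tau_m, double v_r, double tau_ref,
                       double seed) {
  const int n = thresholds.size();
  const int n_steps = (int) std::llround(duration / dt);
  std::mt19937_64 rng((uint64_t) seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> incoming(n, 0.0), incoming_next(n, 0.0);
  std::vector<double> ref_until(n, -1.0);
  std::vector<double> sp_time;
  std::vector<int> sp_id;
  sp_time.reserve(1 << 16);
  sp_id.reserve(1 << 16);

  const double a = std::exp(-dt / tau_m);
  const double noise_amp = std::sqrt(0.5 * sigma * sigma * (1.0 - a * a));
  const double zeta_half = 1.4603545088095868;  // |zeta(1/2)|
  const double th_shift = zeta_half / std::sqrt(2.0 * M_PI)
                          * sigma * std::sqrt(dt / tau_m);
  std::vector<double> th_det(n);
  for (int i = 0; i < n; ++i) th_det[i] = thresholds[i] - th_shift;
  const double two_pi_f = 2.0 * M_PI * f_s / 1000.0;  // f_s in Hz, t in ms

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const double t_end = t + dt;
    const double mu_e_t = (s0 > 0.0) ? mu + s0 * std::sin(two_pi_f * t) : mu;
    for (int i = 0; i < n; ++i) {
      const double xi = gauss(rng);  // drawn unconditionally: refractoriness
                                     // does not desynchronize the stream
      if (t < ref_until[i]) {
        v[i] = v_r;
        continue;
      }
      double vi = v[i] + incoming[i];
      const double mu_i = is_exc[i] ? mu_e_t : mu0;
      vi = mu_i + (vi - mu_i) * a + noise_amp * xi;
      if (vi >= th_det[i]) {
        sp_time.push_back(t_end);
        sp_id.push_back(i + 1);
        vi = v_r;
        ref_until[i] = t_end + tau_ref;
        for (int k = w_p[i]; k < w_p[i + 1]; ++k)
          incoming_next[w_i[k]] += w_x[k];
      }
      v[i] = vi;
    }
    std::copy(incoming_next.begin(), incoming_next.end(), incoming.begin());
    std::fill(incoming_next.begin(), incoming_next.end(), 0.0);
  }

  return List::create(_["time"] = NumericVector(sp_time.begin(), sp_time.end()),
                      _["neuron"] = IntegerVector(sp_id.begin(), sp_id.end()));
}
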