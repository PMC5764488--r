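#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Euler simulation of N all-to-all inhibitory QIF neurons,
//   tau_m * dV_i/dt = V_i^2 + eta_i - J * tau_m * S,
// with threshold/reset at +/- V_theta, refractory hold 2*tau_m/V_theta,
// trailing-window population rate estimator (window tau_s) and shared
// first-order synaptic gating tau_d * dS/dt = -S + R.
//
// Spike times are recorded at the threshold-crossing step ("crossing"
// convention) or half-way through the refractory hold ("midpoint"),
// approximating the transit through +infinity.
//
// Rates are in 1/ms internally; conversion to Hz happens in R.
// [[Rcpp::export]]
List qif_net_sim(NumericVector eta, double tau_m, double J, double tau_d,
                 double V_theta, double dt, double duration, double tau_s,
                 NumericVector v0, double s0, double record_dt,
                 bool return_raster, bool spike_at_midpoint) {
  const int N = eta.size();
  const long n_steps = (long)std::llround(duration / dt);
  const int n_ref = std::max(1, (int)std::llround(2.0 * tau_m / V_theta / dt));
  const int n_win = std::max(1, (int)std::llround(tau_s / dt));
  const int out_every = std::max(1, (int)std::llround(record_dt / dt));
  const double mid_offset = 0.5 * n_ref * dt;

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<int> refr(N, 0);        // remaining refractory steps
  std::vector<int> win(n_win, 0);     // circular buffer of per-step counts
  double S = s0;

  std::vector<double> out_t, out_r, out_s, out_v;
  out_t.reserve(n_steps / out_every + 2);
  out_r.reserve(n_steps / out_every + 2);
  out_s.reserve(n_steps / out_every + 2);
  out_v.reserve(n_steps / out_every + 2);
  std::vector<int> sp_i;
  std::vector<double> sp_t;

  long win_count = 0;
  int win_pos = 0;
  const double rate_norm = 1.0 / (N * n_win * dt);  // spikes -> 1/ms

  for (long step = 0; step < n_steps; ++step) {
    const double t_next = (step + 1) * dt;
    const double I_syn = J * tau_m * S;
    int n_spikes = 0;

    for (int i = 0; i < N; ++i) {
      if (refr[i] > 0) {
        if (--refr[i] == 0) V[i] = -V_theta;
        continue;
      }
      double v = V[i];
      v += dt * (v * v + eta[i] - I_syn) / tau_m;
      if (v >= V_theta) {
        ++n_spikes;
        refr[i] = n_ref;
        V[i] = V_theta;  // held; re-enters at -V_theta after refractory
        if (return_raster) {
          sp_i.push_back(i + 1);
          sp_t.push_back(spike_at_midpoint ? t_next + mid_offset : t_next);
        }
      } else {
        V[i] = v;
      }
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential at t = %f ms (neuron %d)",
             t_next, i + 1);
    }

    // trailing-window rate estimate including this step's spikes
    win_count += n_spikes - win[win_pos];
    win[win_pos] = n_spikes;
    win_pos = (win_pos + 1) % n_win;
    const double R = win_count * rate_norm;

    if (tau_d > 0.0)
      S += dt * (R - S) / tau_d;
    else
      S = R;

    if ((step + 1) % out_every == 0) {
      double vsum = 0.0;
      int n_act = 0;
      for (int i = 0; i < N; ++i)
        if (refr[i] == 0) { vsum += V[i]; ++n_act; }
      out_t.push_back(t_next);
      out_r.push_back(R);
      out_s.push_back(S);
      out_v.push_back(n_act > 0 ? vsum / n_act : NA_REAL);
    }
  }

  // refractory neurons re-enter at the reset value for continuation runs
  NumericVector v_final(N);
  for (int i = 0; i < N; ++i) v_final[i] = refr[i] > 0 ? -V_theta : V[i];

  return List::create(
      _["time"] = out_t, _["r"] = out_r, _["s"] = out_s, _["v_mean"] = out_v,
      _["spike_neuron"] = sp_i, _["spike_time"] = sp_t,
      _["v_final"] = v_final, _["s_final"] = S);
}
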