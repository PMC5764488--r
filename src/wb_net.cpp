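#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Wang-Buzsaki conductance-based interneuron network (Euler method).
//
//   Cm dV_i/dt = -I_Na - I_K - I_L - I_syn + I_app,i + I0
//
// with I_Na = gNa * m_inf^3 * h * (V - ENa), I_K = gK * n^4 * (V - EK),
// I_L = gL * (V - EL), and an inhibitory synaptic current I_syn = k*Cm*S
// shared by all neurons.  S follows tau_d * dS/dt = -S + R where R is the
// trailing-window population rate estimate (window tau_s) built from
// upward 0 mV crossings (spike times linearly interpolated between steps).
//
// The gating rate functions have removable singularities at V = -35 mV
// (alpha_m) and V = -34 mV (alpha_n); the analytic limits are used there.

static inline double alpha_m(double V) {
  double x = V + 35.0;
  if (std::fabs(x) < 1e-7) return 1.0;
  return -0.1 * x / (std::exp(-0.1 * x) - 1.0);
}
static inline double beta_m(double V) { return 4.0 * std::exp(-(V + 60.0) / 18.0); }
static inline double alpha_h(double V) { return 0.07 * std::exp(-(V + 58.0) / 20.0); }
static inline double beta_h(double V) { return 1.0 / (std::exp(-0.1 * (V + 28.0)) + 1.0); }
static inline double alpha_n(double V) {
  double x = V + 34.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return -0.01 * x / (std::exp(-0.1 * x) - 1.0);
}
static inline double beta_n(double V) { return 0.125 * std::exp(-(V + 44.0) / 80.0); }

// Piecewise-linear tables for the voltage-dependent gating rates.  Step
// 0.005 mV over [-130, 60] mV keeps the interpolation error ~1e-9 of the
// function value; outside the range the exact expressions are used.
namespace {
struct RateTables {
  static const int n = 38001;
  double lo = -130.0, hi = 60.0, step = 0.005, inv_step = 200.0;
  std::vector<double> minf, ah, bh, an, bn;
  RateTables() : minf(n), ah(n), bh(n), an(n), bn(n) {
    for (int i = 0; i < n; ++i) {
      double V = lo + i * step;
      double am = alpha_m(V), bm = beta_m(V);
      minf[i] = am / (am + bm);
      ah[i] = alpha_h(V);
      bh[i] = beta_h(V);
      an[i] = alpha_n(V);
      bn[i] = beta_n(V);
    }
  }
};
static RateTables tab;
}  // namespace

// [[Rcpp::export]]
List wb_net_sim(NumericVector I_app, double Cm, double gL, double EL,
                double gNa, double ENa, double gK, double EK, double phi,
                double I0, double k, double tau_d, double dt, double duration,
                double tau_s, NumericVector v0, double s0, double record_dt,
                bool return_raster, bool use_tables,
                NumericVector h0, NumericVector n0) {
  const int N = I_app.size();
  const long n_steps = (long)std::llround(duration / dt);
  const int n_win = std::max(1, (int)std::llround(tau_s / dt));
  const int out_every = std::max(1, (int)std::llround(record_dt / dt));

  std::vector<double> V(v0.begin(), v0.end()), h(N), n_gate(N);
  const bool have_gates = h0.size() == N && n0.size() == N;
  for (int i = 0; i < N; ++i) {
    // gates default to their voltage-dependent steady states (m is
    // instantaneous, m = m_inf, so only h and n carry state)
    h[i] = have_gates ? h0[i]
                      : alpha_h(V[i]) / (alpha_h(V[i]) + beta_h(V[i]));
    n_gate[i] = have_gates ? n0[i]
                           : alpha_n(V[i]) / (alpha_n(V[i]) + beta_n(V[i]));
  }
  double S = s0;

  std::vector<int> win(n_win, 0);
  long win_count = 0;
  int win_pos = 0;
  const double rate_norm = 1.0 / (N * n_win * dt);

  std::vector<double> out_t, out_r, out_s, out_v;
  std::vector<int> sp_i;
  std::vector<double> sp_t;
  out_t.reserve(n_steps / out_every + 2);
  out_r.reserve(n_steps / out_every + 2);
  out_s.reserve(n_steps / out_every + 2);
  out_v.reserve(n_steps / out_every + 2);

  for (long step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const double I_syn = k * Cm * S;
    int n_spikes = 0;
    double vsum = 0.0;

    for (int i = 0; i < N; ++i) {
      const double Vi = V[i];
      double minf, ah, bh, an, bn;
      if (use_tables && Vi > tab.lo && Vi < tab.hi) {
        const double x = (Vi - tab.lo) * tab.inv_step;
        const int j = (int)x;
        const double w = x - j;
        minf = tab.minf[j] + w * (tab.minf[j + 1] - tab.minf[j]);
        ah = tab.ah[j] + w * (tab.ah[j + 1] - tab.ah[j]);
        bh = tab.bh[j] + w * (tab.bh[j + 1] - tab.bh[j]);
        an = tab.an[j] + w * (tab.an[j + 1] - tab.an[j]);
        bn = tab.bn[j] + w * (tab.bn[j + 1] - tab.bn[j]);
      } else {
        const double am = alpha_m(Vi), bm = beta_m(Vi);
        minf = am / (am + bm);
        ah = alpha_h(Vi); bh = beta_h(Vi);
        an = alpha_n(Vi); bn = beta_n(Vi);
      }
      const double m3 = minf * minf * minf;
      const double I_Na = gNa * m3 * h[i] * (Vi - ENa);
      const double n2 = n_gate[i] * n_gate[i];
      const double I_K = gK * n2 * n2 * (Vi - EK);
      const double I_L = gL * (Vi - EL);
      const double Vnew =
          Vi + dt * (-I_Na - I_K - I_L - I_syn + I_app[i] + I0) / Cm;
      h[i] += dt * phi * (ah * (1.0 - h[i]) - bh * h[i]);
      n_gate[i] += dt * phi * (an * (1.0 - n_gate[i]) - bn * n_gate[i]);
      // rate-equation structure keeps gates in [0,1]; enforce against
      // forward-Euler overshoot at extreme voltages
      if (h[i] < 0.0) h[i] = 0.0; else if (h[i] > 1.0) h[i] = 1.0;
      if (n_gate[i] < 0.0) n_gate[i] = 0.0; else if (n_gate[i] > 1.0) n_gate[i] = 1.0;
      if (Vi < 0.0 && Vnew >= 0.0) {
        ++n_spikes;
        if (return_raster) {
          sp_i.push_back(i + 1);
          sp_t.push_back(t + dt * (0.0 - Vi) / (Vnew - Vi));
        }
      }
      V[i] = Vnew;
      vsum += Vnew;
      if (!std::isfinite(Vnew))
        stop("non-finite membrane potential at t = %f ms (neuron %d)",
             t + dt, i + 1);
    }

    win_count += n_spikes - win[win_pos];
    win[win_pos] = n_spikes;
    win_pos = (win_pos + 1) % n_win;
    const double R = win_count * rate_norm;

    if (tau_d > 0.0)
      S += dt * (R - S) / tau_d;
    else
      S = R;

    if ((step + 1) % out_every == 0) {
      out_t.push_back((step + 1) * dt);
      out_r.push_back(R);
      out_s.push_back(S);
      out_v.push_back(vsum / N);
    }
  }

  return List::create(
      _["time"] = out_t, _["r"] = out_r, _["s"] = out_s, _["v_mean"] = out_v,
      _["spike_neuron"] = sp_i, _["spike_time"] = sp_t,
      _["v_final"] = NumericVector(V.begin(), V.end()),
      _["h_final"] = NumericVector(h.begin(), h.end()),
      _["n_final"] = NumericVector(n_gate.begin(), n_gate.end()),
      _["s_final"] = S);
}

// Spike count of a single isolated WB neuron under constant drive,
// after discarding an initial transient.  Used for rheobase bisection.
// [[Rcpp::export]]
int wb_single_spike_count(double I_const, double Cm, double gL, double EL,
                          double gNa, double ENa, double gK, double EK,
                          double phi, double dt, double discard_ms,
                          double probe_ms, double v_init) {
  const long n_steps = (long)std::llround((discard_ms + probe_ms) / dt);
  double V = v_init;
  double h = alpha_h(V) / (alpha_h(V) + beta_h(V));
  double n = alpha_n(V) / (alpha_n(V) + beta_n(V));
  int count = 0;
  for (long step = 0; step < n_steps; ++step) {
    const double am = alpha_m(V), bm = beta_m(V);
    const double minf = am / (am + bm);
    const double m3 = minf * minf * minf;
    const double n2 = n * n;
    const double Vnew =
        V + dt * (-gNa * m3 * h * (V - ENa) - gK * n2 * n2 * (V - EK) -
                  gL * (V - EL) + I_const) / Cm;
    h += dt * phi * (alpha_h(V) * (1.0 - h) - beta_h(V) * h);
    n += dt * phi * (alpha_n(V) * (1.0 - n) - beta_n(V) * n);
    if (V < 0.0 && Vnew >= 0.0 && step * dt >= discard_ms) ++count;
    V = Vnew;
  }
  return count;
}
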