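#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Core fixed-step integrator for the recurrent QIF network with the
// memristive plasticity rule.
//
// Units: time in ms at the interface, voltages in V, currents in A,
// capacitance in F, leak coefficient in A/V^2.  The membrane derivative is
// computed in V/s and scaled by dt in seconds.
//
// Per step:
//   1. snapshot u (start-of-step values serve as V_post for plasticity);
//   2. advance every non-refractory neuron one classical RK4 step under its
//      summed external + internal current (held constant over the step);
//   3. neurons reaching theta_thres spike: their outgoing weights receive one
//      forward-Euler plasticity event of duration tau_event against the
//      snapshot potentials, a normalized rectangular current pulse is queued
//      to all partners, and the membrane is reset and held refractory;
//   4. with the continuous leak enabled all weights decay exponentially
//      (applied lazily in closed form between weight-touching events).

static inline double clampw(double w, double lo, double hi) {
  return w < lo ? lo : (w > hi ? hi : w);
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericMatrix omega_in,
                List neuron, List plast,
                NumericVector seg_dur_ms, NumericMatrix seg_I, int repeats,
                double dt_ms, double I0_int, double pulse_width_ms,
                bool leak, double snapshot_every_ms,
                bool record_traces, int trace_every,
                NumericVector u_init) {
  const int n = omega_in.nrow();
  NumericMatrix omega(clone(omega_in));

  const double Cm     = as<double>(neuron["C"]);
  const double gL     = as<double>(neuron["g_L"]);
  const double u_rest = as<double>(neuron["u_rest"]);
  const double u_crit = as<double>(neuron["u_critical"]);
  const double theta  = as<double>(neuron["theta_thres"]);
  const double t_ref  = as<double>(neuron["t_ref"]);

  const double k_rate = as<double>(plast["k"]);
  const double kappa  = as<double>(plast["kappa"]);
  const double w_min  = as<double>(plast["omega_min"]);
  const double w_max  = as<double>(plast["omega_max"]);
  const double V_crit = as<double>(plast["V_critical"]);
  const double tau_ev = as<double>(plast["tau_event"]);

  const int n_seg = seg_dur_ms.size();
  std::vector<double> seg_end(n_seg);
  double cyc = 0.0;
  for (int s = 0; s < n_seg; ++s) { cyc += seg_dur_ms[s]; seg_end[s] = cyc; }
  const double total_ms = cyc * repeats;
  const long n_steps = (long) std::llround(total_ms / dt_ms);

  const double dt_s = dt_ms * 1e-3;
  const int ref_steps = (int) std::llround(t_ref / dt_ms);
  const int pulse_steps = std::max(1, (int) std::llround(pulse_width_ms / dt_ms));
  const long snap_steps = snapshot_every_ms > 0
    ? std::max((long)1, (long) std::llround(snapshot_every_ms / dt_ms)) : 0;

  std::vector<double> u(n), u0(n), I_ext(n), I_int(n, 0.0);
  std::vector<int> refrac(n, 0);
  for (int i = 0; i < n; ++i) u[i] = u_init[i];

  std::deque< std::pair<long, std::vector<double> > > pulses;

  std::vector<int> sp_id; std::vector<double> sp_t;
  List snaps; std::vector<double> snap_t;

  long n_trace = 0;
  if (record_traces) n_trace = n_steps / trace_every + 1;
  NumericMatrix traces(record_traces ? n_trace : 0, record_traces ? n : 0);
  NumericVector trace_t(record_traces ? n_trace : 0);
  long trace_row = 0;
  if (record_traces) {
    for (int i = 0; i < n; ++i) traces(0, i) = u[i];
    trace_t[0] = 0.0; trace_row = 1;
  }

  double last_decay_t = 0.0;
  const bool do_leak = leak && kappa > 0.0;
  // bring all weights up to date with the continuous leak
  auto decay_to = [&](double t_now) {
    if (!do_leak || t_now <= last_decay_t) return;
    const double f = std::exp(-kappa * (t_now - last_decay_t));
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j) {
          double w = omega(i, j) * f;
          omega(i, j) = w < w_min ? w_min : w;
        }
    last_decay_t = t_now;
  };

  std::vector<int> spiked; spiked.reserve(n);

  for (long step = 0; step < n_steps; ++step) {
    const double t = step * dt_ms;
    const double t_end = t + dt_ms;

    // external current from the (cyclic) stimulus program
    const double t_cyc = t - cyc * std::floor(t / cyc);
    int cur_seg = 0;
    while (cur_seg < n_seg - 1 && t_cyc >= seg_end[cur_seg] - 1e-9) ++cur_seg;

    // expire finished internal-current pulses
    while (!pulses.empty() && pulses.front().first <= step) {
      const std::vector<double>& d = pulses.front().second;
      for (int i = 0; i < n; ++i) I_int[i] -= d[i];
      pulses.pop_front();
    }

    spiked.clear();
    for (int i = 0; i < n; ++i) u0[i] = u[i];

    for (int i = 0; i < n; ++i) {
      if (refrac[i] > 0) { u[i] = u_rest; --refrac[i]; continue; }
      const double I = seg_I(cur_seg, i) + I_int[i];
      // classical RK4, current held constant across the step
      const double k1 = (gL * (u[i] - u_rest) * (u[i] - u_crit) + I) / Cm;
      double um = u[i] + 0.5 * dt_s * k1;
      const double k2 = (gL * (um - u_rest) * (um - u_crit) + I) / Cm;
      um = u[i] + 0.5 * dt_s * k2;
      const double k3 = (gL * (um - u_rest) * (um - u_crit) + I) / Cm;
      um = u[i] + dt_s * k3;
      const double k4 = (gL * (um - u_rest) * (um - u_crit) + I) / Cm;
      u[i] += dt_s * (k1 + 2.0 * k2 + 2.0 * k3 + k4) / 6.0;
      if (u[i] >= theta) spiked.push_back(i);
    }

    if (!spiked.empty()) {
      decay_to(t_end);
      std::vector<double> delta(n, 0.0);
      if (I0_int > 0.0) {
        // Eq.-style normalization: neuron j receives
        //   I0_int * sum_{i spiking} omega_ij / sum_i omega_ij
        for (int j = 0; j < n; ++j) {
          double colsum = 0.0;
          for (int i = 0; i < n; ++i) colsum += omega(i, j);
          if (colsum <= 0.0) { delta[j] = 0.0; continue; }
          double num = 0.0;
          for (size_t s = 0; s < spiked.size(); ++s) num += omega(spiked[s], j);
          delta[j] = I0_int * num / colsum;
        }
      }
      // plasticity: outgoing row of every spiker against snapshot potentials
      for (size_t s = 0; s < spiked.size(); ++s) {
        const int i = spiked[s];
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          const double w = omega(i, j);
          const double f = k_rate * (u0[j] - V_crit) * w * w * (1.0 - w / w_max);
          omega(i, j) = clampw(w + (f - kappa * w) * tau_ev, w_min, w_max);
        }
      }
      if (I0_int > 0.0) {
        for (int i = 0; i < n; ++i) I_int[i] += delta[i];
        // active during the next pulse_steps integration steps
        pulses.push_back(std::make_pair(step + pulse_steps + 1, delta));
      }
      for (size_t s = 0; s < spiked.size(); ++s) {
        const int i = spiked[s];
        sp_id.push_back(i + 1);
        sp_t.push_back(t_end);
        u[i] = u_rest;
        refrac[i] = ref_steps;
      }
    }

    if (snap_steps > 0 && ((step + 1) % snap_steps == 0)) {
      decay_to(t_end);
      snaps.push_back(clone(omega));
      snap_t.push_back(t_end);
    }
    if (record_traces && ((step + 1) % trace_every == 0) && trace_row < n_trace) {
      for (int i = 0; i < n; ++i) traces(trace_row, i) = u[i];
      trace_t[trace_row] = t_end;
      ++trace_row;
    }
  }
  decay_to(n_steps * dt_ms);

  List out = List::create(
    _["spike_id"] = wrap(sp_id),
    _["spike_t"]  = wrap(sp_t),
    _["omega"]    = omega,
    _["snapshots"] = snaps,
    _["snapshot_t"] = wrap(snap_t),
    _["duration_ms"] = total_ms);
  if (record_traces) {
    out["traces"] = traces;
    out["trace_t"] = trace_t;
  }
  return out;
}
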