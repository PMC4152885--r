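// Fixed-step network integrator for the virtual transceiver chip:
// leaky integrate-and-fire somas with current-based exponential synapses.
//   dv/dt = (-v + R * I_total) / tau_m        (forward Euler, step dt)
//   dI_k/dt = -I_k / tau_s[k]                 (exact exponential decay)
// An input event on channel k of neuron i adds its weight to I_k[i].
// Spikes (v >= theta) reset v to v_reset, start a refractory hold, and
// propagate over the routing table with a one-step delay. Determinism:
// fixed iteration order, R's RNG for the optional Gaussian current noise.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List sim_lif_core(int n, double dt, int n_steps,
                  NumericVector tau_m, NumericVector r_in,
                  NumericVector theta, NumericVector v_reset,
                  NumericVector t_ref, NumericVector i_const,
                  NumericVector tau_s,
                  IntegerVector st_step, IntegerVector st_neuron,
                  IntegerVector st_chan, NumericVector st_w,
                  IntegerVector r_ptr, IntegerVector r_dst,
                  IntegerVector r_chan, NumericVector r_w,
                  double noise_sd, bool record, int record_neuron) {
  const int K = tau_s.size();
  std::vector<double> v(n, 0.0);
  std::vector<double> I(static_cast<size_t>(K) * n, 0.0);
  std::vector<int> refc(n, 0);
  std::vector<double> decay(K), ref_steps(n);
  for (int k = 0; k < K; ++k) decay[k] = std::exp(-dt / tau_s[k]);
  for (int i = 0; i < n; ++i) ref_steps[i] = std::max(0.0, std::round(t_ref[i] / dt));

  std::vector<int> spike_neuron, spike_step;
  spike_neuron.reserve(1024);
  spike_step.reserve(1024);

  // spikes from step t-1 land on their targets at step t
  std::vector<int> pend_dst, pend_chan;
  std::vector<double> pend_w;

  NumericVector v_trace(record ? n_steps : 0);
  NumericVector i_trace(record ? n_steps : 0);

  const int n_st = st_step.size();
  int si = 0;
  const bool noisy = noise_sd > 0.0;

  for (int t = 0; t < n_steps; ++t) {
    // deliver stimulus events scheduled for this step
    while (si < n_st && st_step[si] == t) {
      I[static_cast<size_t>(st_chan[si]) * n + st_neuron[si]] += st_w[si];
      ++si;
    }
    // deliver delayed spike propagations
    for (size_t p = 0; p < pend_dst.size(); ++p)
      I[static_cast<size_t>(pend_chan[p]) * n + pend_dst[p]] += pend_w[p];
    pend_dst.clear(); pend_chan.clear(); pend_w.clear();

    // integrate and detect threshold crossings
    for (int i = 0; i < n; ++i) {
      if (refc[i] > 0) { --refc[i]; v[i] = v_reset[i]; continue; }
      double itot = i_const[i];
      for (int k = 0; k < K; ++k) itot += I[static_cast<size_t>(k) * n + i];
      if (noisy) itot += noise_sd * norm_rand();
      v[i] += dt * (-v[i] + r_in[i] * itot) / tau_m[i];
      if (v[i] >= theta[i]) {
        spike_neuron.push_back(i);
        spike_step.push_back(t);
        v[i] = v_reset[i];
        refc[i] = static_cast<int>(ref_steps[i]);
        for (int e = r_ptr[i]; e < r_ptr[i + 1]; ++e) {
          pend_dst.push_back(r_dst[e]);
          pend_chan.push_back(r_chan[e]);
          pend_w.push_back(r_w[e]);
        }
      }
    }
    if (record) {
      v_trace[t] = v[record_neuron];
      double itot = 0.0;
      for (int k = 0; k < K; ++k)
        itot += I[static_cast<size_t>(k) * n + record_neuron];
      i_trace[t] = itot;
    }
    // decay synaptic currents
    for (int k = 0; k < K; ++k) {
      double d = decay[k];
      double* Ik = &I[static_cast<size_t>(k) * n];
      for (int i = 0; i < n; ++i) Ik[i] *= d;
    }
  }

  return List::create(_["spike_neuron"] = wrap(spike_neuron),
                      _["spike_step"] = wrap(spike_step),
                      _["v_trace"] = v_trace,
                      _["i_trace"] = i_trace);
}
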