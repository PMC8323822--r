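#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of a network of Izhikevich neurons:
//   v' = 0.04 v^2 + 5 v + 140 - u + I,   u' = a (b v - u)
// with spike-and-reset at v >= 30 mV (v <- c, u <- u + d) and delayed
// delta-current synapses: a spike on edge (src -> dst, weight w, delay
// delta) adds w to I_dst for exactly one integration step, delta ms after
// the threshold crossing. Noise is an independent Gaussian current per
// neuron and step drawn from R's RNG (seeded by the caller).
//
// [[Rcpp::export(name = ".izh_simulate")]]
List izh_simulate(int n,
                  IntegerVector edge_src, IntegerVector edge_dst,
                  NumericVector edge_w, IntegerVector edge_delay_steps,
                  NumericVector a, NumericVector b,
                  NumericVector c, NumericVector d,
                  double duration_ms, double dt,
                  double noise_amp, NumericVector i_bias,
                  double release_prob, bool record_v) {
  const int n_steps = (int)std::ceil(duration_ms / dt);
  const int n_edges = edge_src.size();

  int max_delay = 1;
  for (int e = 0; e < n_edges; ++e)
    if (edge_delay_steps[e] > max_delay) max_delay = edge_delay_steps[e];
  const int buf_len = max_delay + 1;

  // outgoing adjacency as CSR for fast spike propagation
  std::vector<int> out_count(n, 0);
  for (int e = 0; e < n_edges; ++e) out_count[edge_src[e]]++;
  std::vector<int> out_start(n + 1, 0);
  for (int i = 0; i < n; ++i) out_start[i + 1] = out_start[i] + out_count[i];
  std::vector<int> out_edge(n_edges);
  {
    std::vector<int> fill(out_start.begin(), out_start.end() - 1);
    for (int e = 0; e < n_edges; ++e) out_edge[fill[edge_src[e]]++] = e;
  }

  std::vector<double> v(n), u(n);
  for (int i = 0; i < n; ++i) { v[i] = -65.0; u[i] = b[i] * v[i]; }

  // ring buffer of pending synaptic currents, [slot][neuron]
  std::vector< std::vector<double> > syn(buf_len, std::vector<double>(n, 0.0));

  std::vector< std::vector<double> > spikes(n);
  NumericVector v_trace;
  if (record_v) v_trace = NumericVector(n_steps);

  RNGScope scope;

  for (int s = 0; s < n_steps; ++s) {
    const int slot = s % buf_len;
    const double t_ms = s * dt;
    for (int i = 0; i < n; ++i) {
      double I = i_bias[i] + syn[slot][i];
      if (noise_amp > 0.0) I += noise_amp * norm_rand();
      double vi = v[i], ui = u[i];
      double vnew = vi + dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      double unew = ui + dt * (a[i] * (b[i] * vi - ui));
      if (!std::isfinite(vnew) || !std::isfinite(unew))
        stop("non-finite state at t = %.2f ms, neuron %d: "
             "unstable dt/weight combination", t_ms, i);
      if (vnew >= 30.0) {
        // sub-step threshold-crossing time by linear interpolation keeps
        // spike times off the integration-step comb, so correlogram shape
        // reflects timing statistics rather than grid quantisation
        double frac = (30.0 - vi) / (vnew - vi);
        if (frac < 0.0) frac = 0.0;
        if (frac > 0.999) frac = 0.999;
        spikes[i].push_back(t_ms + frac * dt);
        vnew = c[i];
        unew += d[i];
        // schedule delayed synaptic currents on all outgoing edges;
        // transmission is probabilistic (vesicle-release failure)
        for (int q = out_start[i]; q < out_start[i + 1]; ++q) {
          const int e = out_edge[q];
          if (release_prob < 1.0 && unif_rand() >= release_prob) continue;
          const int tgt_slot = (s + edge_delay_steps[e]) % buf_len;
          syn[tgt_slot][edge_dst[e]] += edge_w[e];
        }
      }
      v[i] = vnew;
      u[i] = unew;
    }
    if (record_v) v_trace[s] = v[0];
    // clear the slot just consumed for reuse one buffer-cycle later
    std::fill(syn[slot].begin(), syn[slot].end(), 0.0);
  }

  List out(n);
  for (int i = 0; i < n; ++i) out[i] = wrap(spikes[i]);
  if (record_v)
    return List::create(_["spikes_ms"] = out, _["v_trace"] = v_trace);
  return List::create(_["spikes_ms"] = out);
}
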