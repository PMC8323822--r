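#' Simulate a network of Izhikevich neurons
#'
#' Integrates the Izhikevich model (v' = 0.04 v^2 + 5 v + 140 - u + I,
#' u' = a (b v - u), spike-and-reset at v >= 30 mV) with forward Euler at
#' step `dt` ms. Each presynaptic spike on an edge (j -> k, weight w,
#' delay delta) injects a current pulse of amplitude w into neuron k for
#' exactly one integration step, delta ms after the spike (delays are
#' rounded to integration steps, minimum one step). Every neuron
#' additionally receives an independent Gaussian noise current of standard
#' deviation `noise_amplitude` per step, plus an optional constant bias.
#' Synaptic transmission is probabilistic: each presynaptic spike is
#' delivered independently with probability `release_prob` per edge
#' (vesicle-release failure), which keeps multi-hop propagation — and hence
#' burst-synchrony artifacts in the correlograms — sub-deterministic, as in
#' real cortical synapses. Spike times are located within the crossing step
#' by linear interpolation of the threshold crossing. The run is
#' deterministic given `seed`.
#'
#' @param model a [network_model()].
#' @param duration recording duration in seconds (>= 1 for meaningful
#'   statistics; shorter runs are allowed for diagnostics).
#' @param dt integration step in ms (must be <= 1).
#' @param noise_amplitude standard deviation of the per-step Gaussian noise
#'   current. The default sustains irregular few-Hz background firing with
#'   intermittent collective bursts in sparse excitatory networks.
#' @param I_bias constant input current, scalar or per-neuron vector.
#' @param release_prob per-spike synaptic transmission probability in
#'   (0, 1].
#' @param seed integer RNG seed.
#' @param record_v if `TRUE`, also return the membrane-potential trace of
#'   neuron 0 (diagnostics).
#' @return a [spike_train_set()]; with `record_v = TRUE`, a list with
#'   fields `trains` and `v_trace`.
#' @export
simulate_izhikevich <- function(model, duration = 300, dt = 0.5,
                                noise_amplitude = 4.5, I_bias = 0,
                                release_prob = 0.4,
                                seed = 1L, record_v = FALSE) {
  stopifnot(inherits(model, "network_model"), dt <= 1, dt > 0,
            duration > 0, noise_amplitude >= 0,
            release_prob > 0, release_prob <= 1)
  n <- model$n_neurons
  if (length(I_bias) == 1) I_bias <- rep(I_bias, n)
  stopifnot(length(I_bias) == n)
  e <- model$edges
  delay_steps <- if (nrow(e)) pmax(1L, as.integer(round(e$delay_ms / dt)))
                 else integer(0)
  set.seed(seed)
  res <- .izh_simulate(n,
                       as.integer(e$src), as.integer(e$dst),
                       as.numeric(e$weight), delay_steps,
                       model$neuron_params$a, model$neuron_params$b,
                       model$neuron_params$c, model$neuron_params$d_reset,
                       duration * 1000, dt, noise_amplitude,
                       as.numeric(I_bias), release_prob, record_v)
  trains <- spike_train_set(lapply(res$spikes_ms, function(t) t / 1000),
                            duration)
  if (record_v) list(trains = trains, v_trace = res$v_trace) else trains
}
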