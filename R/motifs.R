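#' Deterministic spike-motif fixtures
#'
#' Generates small networks with exactly known propagation structure, used
#' as oracles for the correlation and super-selection machinery. A root
#' neuron emits homogeneous-Poisson events; every downstream neuron copies
#' each event shifted by the cumulative motif delay plus independent
#' Gaussian jitter (sd `jitter_sd` ms) accumulated per traversed edge, so
#' that longer indirect paths carry proportionally more phase noise and
#' hence lower, wider correlogram peaks.
#'
#' Motifs (delays in ms, one per edge):
#' * `chain`: 0 -> 1 -> 2 -> ... (length = `length(delays)` + 1).
#' * `common_input`: 0 -> 1, 0 -> 2, ... (root drives all others).
#' * `common_output`: 1 -> 0, 2 -> 0, ... modelled as independent sources
#'   whose events converge on neuron 0 with the given delays.
#' * `pair`: 0 -> 1 (single edge).
#'
#' @param motif one of `"chain"`, `"common_input"`, `"common_output"`,
#'   `"pair"`.
#' @param delays positive per-edge delays in ms.
#' @param event_rate root event rate in Hz.
#' @param jitter_sd per-edge Gaussian jitter sd in ms (>= 0).
#' @param duration recording duration in seconds.
#' @param seed integer RNG seed.
#' @return list with fields `trains` ([spike_train_set()]) and `model`
#'   ([network_model()]) holding the true motif edges.
#' @export
generate_delta_motif <- function(motif = c("chain", "common_input",
                                           "common_output", "pair"),
                                 delays, event_rate = 5, jitter_sd = 0,
                                 duration = 60, seed = 1L) {
  motif <- match.arg(motif)
  stopifnot(all(delays > 0), jitter_sd >= 0, event_rate > 0, duration > 0)
  if (motif == "pair") stopifnot(length(delays) == 1)
  set.seed(seed)
  n_edges <- length(delays)
  n <- n_edges + 1L

  root_events <- function() {
    n_ev <- rpois(1, event_rate * duration)
    sort(runif(n_ev, 0, duration))
  }
  shift <- function(ev, delay_ms, n_jitter_edges) {
    out <- ev + delay_ms / 1000 +
      if (n_jitter_edges > 0 && jitter_sd > 0)
        rnorm(length(ev), 0, jitter_sd * sqrt(n_jitter_edges) / 1000)
      else 0
    sort(out[out >= 0 & out < duration])
  }

  if (motif %in% c("chain", "pair")) {
    ev <- root_events()
    spike_times <- vector("list", n)
    spike_times[[1]] <- ev
    # jitter accumulates along the chain: each traversed edge adds an
    # independent Gaussian term, so neuron i carries the running sum and
    # the i-hop dependency has sd jitter_sd * sqrt(i)
    cum <- ev
    for (i in seq_len(n_edges)) {
      cum <- cum + delays[i] / 1000 +
        if (jitter_sd > 0) rnorm(length(ev), 0, jitter_sd / 1000) else 0
      keep <- cum >= 0 & cum < duration
      spike_times[[i + 1]] <- sort(cum[keep])
    }
    edges <- data.frame(src = 0:(n_edges - 1L), dst = 1:n_edges,
                        weight = 1, delay_ms = delays)
  } else if (motif == "common_input") {
    ev <- root_events()
    spike_times <- c(list(ev),
                     lapply(seq_len(n_edges),
                            function(i) shift(ev, delays[i], 1)))
    edges <- data.frame(src = 0L, dst = 1:n_edges,
                        weight = 1, delay_ms = delays)
  } else { # common_output: independent sources 1..n_edges converge on 0
    src_ev <- replicate(n_edges, root_events(), simplify = FALSE)
    sink_ev <- sort(unlist(lapply(seq_len(n_edges), function(i)
      shift(src_ev[[i]], delays[i], 1))))
    sink_ev <- sink_ev[!duplicated(sink_ev)]
    spike_times <- c(list(sink_ev), src_ev)
    edges <- data.frame(src = 1:n_edges, dst = 0L,
                        weight = 1, delay_ms = delays)
  }
  # enforce strict ordering (jitter could create ties at double precision)
  spike_times <- lapply(spike_times, function(v) v[!duplicated(v)])
  list(trains = spike_train_set(spike_times, duration),
       model = network_model(n, edges))
}
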