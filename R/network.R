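#' Izhikevich neuron parameters
#'
#' The four parameters of the Izhikevich (2003) spiking model: `a` sets the
#' recovery time scale (1/ms), `b` the sensitivity of the recovery variable
#' to the membrane potential, `c` the post-spike reset potential (mV) and
#' `d_reset` the post-spike increment of the recovery variable (named so to
#' avoid collision with the discrimination threshold `d` used in the
#' reconstruction). Presets: `"rs"` (regular spiking, a = 0.02, b = 0.2,
#' c = -65, d_reset = 8) and `"ib"` (intrinsically bursting, c = -55,
#' d_reset = 4).
#'
#' @param a,b,c,d_reset numeric scalars; or use `preset`.
#' @param preset `"rs"` or `"ib"`; overrides the individual arguments.
#' @return named list with fields `a`, `b`, `c`, `d_reset`.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c = -65, d_reset = 8,
                              preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("rs", "ib"))
    if (preset == "rs") { a <- 0.02; b <- 0.2; c <- -65; d_reset <- 8 }
    if (preset == "ib") { a <- 0.02; b <- 0.2; c <- -55; d_reset <- 4 }
  }
  stopifnot(a > 0, c < 30)
  list(a = a, b = b, c = c, d_reset = d_reset)
}

#' Ground-truth network model
#'
#' A directed weighted graph of spiking neurons with per-edge synaptic
#' weights (mV-scale current pulses) and axonal conduction delays (ms),
#' plus per-neuron Izhikevich parameters. Self-loops are rejected.
#'
#' @param n_neurons number of neurons.
#' @param edges data frame with columns `src`, `dst` (0-based ids),
#'   `weight`, `delay_ms`.
#' @param neuron_params data frame with columns `a`, `b`, `c`, `d_reset`
#'   (one row per neuron); defaults to all regular-spiking.
#' @return object of class `network_model` with `n_c` the true edge count.
#' @export
network_model <- function(n_neurons, edges, neuron_params = NULL) {
  stopifnot(n_neurons >= 1)
  edges <- as.data.frame(edges)
  stopifnot(all(c("src", "dst", "weight", "delay_ms") %in% names(edges)))
  if (nrow(edges)) {
    stopifnot(all(edges$src != edges$dst),
              all(edges$src >= 0), all(edges$dst >= 0),
              all(edges$src < n_neurons), all(edges$dst < n_neurons),
              all(edges$delay_ms > 0))
  }
  if (is.null(neuron_params)) {
    p <- izhikevich_params(preset = "rs")
    neuron_params <- data.frame(a = rep(p$a, n_neurons), b = p$b,
                                c = p$c, d_reset = p$d_reset)
  }
  neuron_params <- as.data.frame(neuron_params)
  stopifnot(nrow(neuron_params) == n_neurons,
            all(neuron_params$a > 0), all(neuron_params$c < 30))
  structure(
    list(n_neurons = n_neurons, edges = edges,
         neuron_params = neuron_params, n_c = nrow(edges)),
    class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d neurons, %d directed edges (density %.3f)\n",
              x$n_neurons, x$n_c,
              x$n_c / max(1, x$n_neurons * (x$n_neurons - 1))))
  invisible(x)
}

#' Generate a sparse random directed network
#'
#' Draws `ceiling(mean_out_degree * n_neurons)` directed edges uniformly
#' without replacement over all ordered pairs (no self-loops), with
#' per-edge conduction delays and synaptic weights drawn uniformly from
#' the given ranges. The mean out-degree is held constant across network
#' sizes so that connectivity does not grow with the network, mimicking the
#' sparse regime of cultured networks. Neuron types are assigned at random:
#' 80% regular spiking, 20% intrinsically bursting.
#'
#' @param n_neurons number of neurons (>= 3).
#' @param mean_out_degree average number of outgoing edges per neuron.
#' @param delay_range conduction delay range in ms, default `c(0.3, 0.8)`
#'   (sub-millisecond axonal delays of closely spaced cultured neurons;
#'   together with the ~0.5-1 ms synaptic integration latency this puts
#'   direct correlation lags in the 1-2 ms range).
#' @param weight_range synaptic weight range, default `c(100, 160)`
#'   (current pulse amplitude; the membrane depolarisation per delivered
#'   spike is approximately `weight * dt` mV for integration step `dt` ms,
#'   i.e. a reliably suprathreshold 50-80 mV kick at the default step).
#' @param frac_bursting fraction of intrinsically-bursting neurons.
#' @param seed integer RNG seed; identical inputs and seed give identical
#'   networks.
#' @return a [network_model()].
#' @export
generate_random_network <- function(n_neurons, mean_out_degree = 2,
                                    delay_range = c(0.3, 0.8),
                                    weight_range = c(100, 160),
                                    frac_bursting = 0.2,
                                    seed = 1L) {
  stopifnot(n_neurons >= 3, mean_out_degree > 0,
            length(delay_range) == 2, length(weight_range) == 2,
            all(delay_range > 0))
  n_edges <- as.integer(ceiling(mean_out_degree * n_neurons))
  n_pairs <- n_neurons * (n_neurons - 1)
  if (n_edges > n_pairs)
    stop("requested edge count (", n_edges,
         ") exceeds available ordered pairs (", n_pairs, ")")
  set.seed(seed)
  # ordered pairs enumerated row-major over (src, dst), dst != src
  pick <- sample.int(n_pairs, n_edges)
  src <- (pick - 1L) %/% (n_neurons - 1L)
  off <- (pick - 1L) %% (n_neurons - 1L)
  dst <- ifelse(off >= src, off + 1L, off)
  edges <- data.frame(
    src = as.integer(src), dst = as.integer(dst),
    weight = runif(n_edges, weight_range[1], weight_range[2]),
    delay_ms = runif(n_edges, delay_range[1], delay_range[2]))
  ib <- izhikevich_params(preset = "ib")
  rs <- izhikevich_params(preset = "rs")
  is_ib <- runif(n_neurons) < frac_bursting
  neuron_params <- data.frame(
    a = ifelse(is_ib, ib$a, rs$a), b = ifelse(is_ib, ib$b, rs$b),
    c = ifelse(is_ib, ib$c, rs$c),
    d_reset = ifelse(is_ib, ib$d_reset, rs$d_reset))
  network_model(n_neurons, edges, neuron_params)
}

#' Ground-truth adjacency matrix of a network model
#' @param model a [network_model()].
#' @return binary `n x n` matrix, entry (j+1, k+1) = 1 iff edge j -> k.
#' @export
truth_matrix <- function(model) {
  stopifnot(inherits(model, "network_model"))
  m <- matrix(0L, model$n_neurons, model$n_neurons)
  if (nrow(model$edges))
    m[cbind(model$edges$src + 1L, model$edges$dst + 1L)] <- 1L
  m
}
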