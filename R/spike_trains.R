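#' Spike train set
#'
#' Container for the spiking activity of `n_neurons` neurons over a fixed
#' recording duration. Spike times are in seconds, strictly increasing
#' within each neuron and contained in `[0, duration)`. Neuron ids are
#' 0-based throughout the package, matching the on-disk CSV format.
#'
#' @param spike_times list of numeric vectors, one per neuron (seconds).
#' @param duration recording duration in seconds.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spike_times, duration) {
  stopifnot(is.list(spike_times), is.numeric(duration), duration > 0)
  spike_times <- lapply(spike_times, as.numeric)
  for (i in seq_along(spike_times)) {
    st <- spike_times[[i]]
    if (anyNA(st)) stop("NA spike time for neuron ", i - 1L)
    if (is.unsorted(st, strictly = TRUE))
      stop("spike times of neuron ", i - 1L, " not strictly increasing")
    if (length(st) && (st[1] < 0 || st[length(st)] >= duration))
      stop("spike times of neuron ", i - 1L, " outside [0, duration)")
  }
  structure(
    list(spike_times = spike_times,
         n_neurons = length(spike_times),
         duration = duration),
    class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  ns <- lengths(x$spike_times)
  cat(sprintf("spike_train_set: %d neurons, %.1f s, %d spikes (%.2f Hz mean rate)\n",
              x$n_neurons, x$duration, sum(ns),
              mean(ns) / x$duration))
  invisible(x)
}

#' Total spike counts per neuron
#' @param trains a [spike_train_set()].
#' @return integer vector of per-neuron spike counts.
#' @export
spike_counts <- function(trains) lengths(trains$spike_times)

#' Discretize spike trains into binned count signals
#'
#' Converts each spike train into a regularly sampled signal whose i-th
#' value is the number of spikes falling in `[i * dt, (i + 1) * dt)`
#' (`dt` in milliseconds). All signals share the same number of samples,
#' spanning the full recording, so that pairwise correlations are computed
#' on a common grid.
#'
#' @param trains a [spike_train_set()].
#' @param dt bin width in milliseconds.
#' @return list of `spike_signal` objects (fields `values`, `dt_ms`,
#'   `n_samples`).
#' @export
bin_spikes <- function(trains, dt) {
  stopifnot(inherits(trains, "spike_train_set"), dt > 0)
  n_samples <- as.integer(ceiling(trains$duration * 1000 / dt))
  lapply(trains$spike_times, function(st) {
    idx <- spike_bin_indices(st, dt)
    values <- integer(n_samples)
    if (length(idx)) {
      tab <- tabulate(idx + 1L, nbins = n_samples)
      values <- tab
    }
    structure(list(values = values, dt_ms = dt, n_samples = n_samples),
              class = "spike_signal")
  })
}

# 0-based bin index of each spike at bin width dt (ms); times in seconds
spike_bin_indices <- function(times_s, dt) {
  as.integer(floor(times_s * 1000 / dt + 1e-9))
}
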