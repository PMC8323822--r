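#' Correlation function container
#'
#' A pairwise correlation function sampled on a symmetric lag grid
#' (step `dt_ms`, odd length). Sign convention: a peak at positive lag
#' means the activity of neuron `j` (first of `pair`) precedes that of
#' neuron `k`.
#'
#' @param lags lag grid in ms, symmetric about 0.
#' @param values correlation values (finite).
#' @param mode `"raw"` or `"pearson"`.
#' @param pair integer pair `c(j, k)` of 0-based neuron ids.
#' @param dt_ms lag grid step in ms.
#' @return object of class `correlation_function`.
#' @export
correlation_function <- function(lags, values, mode, pair, dt_ms) {
  stopifnot(length(lags) == length(values), length(lags) %% 2 == 1,
            all(is.finite(values)))
  structure(list(lags = lags, values = values, mode = mode,
                 pair = as.integer(pair), dt_ms = dt_ms),
            class = "correlation_function")
}

#' @export
print.correlation_function <- function(x, ...) {
  cat(sprintf("correlation_function (%s): pair (%d, %d), lags %.2f..%.2f ms (step %.3f)\n",
              x$mode, x$pair[1], x$pair[2], min(x$lags), max(x$lags), x$dt_ms))
  invisible(x)
}

#' Cross-correlation of two binned spike signals
#'
#' Computes the linear (zero-padded, not circular) cross-correlation
#' `R(tau) = sum_t s_j(t) s_k(t + tau)` on a symmetric lag grid via the
#' FFT correlation theorem. In `"pearson"` mode the value at each lag is
#' the Pearson coefficient of the lag-shifted overlapping segments of the
#' two signals (lags where either segment has zero variance yield 0).
#'
#' @param sig_j,sig_k `spike_signal` objects with equal `dt_ms` and
#'   `n_samples` (see [bin_spikes()]).
#' @param mode `"raw"` or `"pearson"`.
#' @param max_lag_ms optional largest |lag| to return; defaults to the full
#'   grid (`n_samples - 1` bins).
#' @param pair 0-based ids `c(j, k)` recorded in the result.
#' @return a [correlation_function()].
#' @export
cross_correlation <- function(sig_j, sig_k, mode = c("raw", "pearson"),
                              max_lag_ms = NULL, pair = c(0L, 1L)) {
  mode <- match.arg(mode)
  stopifnot(sig_j$dt_ms == sig_k$dt_ms, sig_j$n_samples == sig_k$n_samples)
  dt <- sig_j$dt_ms
  S <- sig_j$n_samples
  L <- if (is.null(max_lag_ms)) S - 1L
       else min(S - 1L, as.integer(floor(max_lag_ms / dt)))
  if (mode == "pearson" &&
      (sum(sig_j$values) < 2 || sum(sig_k$values) < 2))
    stop("pearson mode requires signals with at least 2 spikes")

  x <- as.numeric(sig_j$values)
  y <- as.numeric(sig_k$values)
  N <- stats::nextn(S + L, c(2, 3, 5))
  X <- fft(c(x, numeric(N - S)))
  Y <- fft(c(y, numeric(N - S)))
  cc <- Re(fft(Conj(X) * Y, inverse = TRUE)) / N
  # cc[1 + l] = sum_t x(t) y(t + l) for l >= 0; negative lags wrap around
  raw <- c(cc[N - (L:1) + 1L], cc[1:(L + 1L)])
  lags <- (-L:L) * dt
  if (mode == "raw")
    return(correlation_function(lags, raw, "raw", pair, dt))

  vals <- pearsonize(raw, -L:L, S,
                     dense_prefix(x), dense_prefix(y))
  correlation_function(lags, vals, "pearson", pair, dt)
}

# sparse_prefix-compatible accessor for a dense signal vector
dense_prefix <- function(v) {
  nz <- which(v != 0)
  list(ub = nz - 1L, csum = cumsum(v[nz]), csum2 = cumsum(v[nz]^2),
       total = sum(v), total2 = sum(v^2))
}

# Prefix-sum accessor for a sparse binned signal: cumulative sum of counts
# and squared counts up to an arbitrary bin, without materialising the
# dense signal. `bins` are the sorted (0-based) occupied bin indices with
# multiplicity.
sparse_prefix <- function(bins) {
  r <- rle(bins)
  ub <- r$values
  cnt <- as.numeric(r$lengths)
  list(ub = ub, csum = cumsum(cnt), csum2 = cumsum(cnt^2),
       total = sum(cnt), total2 = sum(cnt^2))
}

# sums of s and s^2 over the 0-based bin range [a, b] (vectors)
sparse_range_sums <- function(pf, a, b) {
  hi <- findInterval(b, pf$ub)
  lo <- findInterval(a - 1L, pf$ub)
  s <- ifelse(hi > 0, pf$csum[pmax(hi, 1L)], 0) -
       ifelse(lo > 0, pf$csum[pmax(lo, 1L)], 0)
  s2 <- ifelse(hi > 0, pf$csum2[pmax(hi, 1L)], 0) -
        ifelse(lo > 0, pf$csum2[pmax(lo, 1L)], 0)
  list(s = s, s2 = s2)
}

# Convert raw lagged products into per-lag Pearson coefficients over the
# overlapping segments. `pfx`, `pfy` are sparse_prefix() objects of the two
# binned signals; lags where either segment has zero variance yield 0.
pearsonize <- function(raw, lag_bins, S, pfx, pfy) {
  l <- lag_bins
  n <- S - abs(l)
  # x overlaps 0-based bins [max(0, -l) .. ], y the range shifted by +l
  xa <- pmax(0L, -l); xb <- xa + n - 1L
  ya <- pmax(0L, l);  yb <- ya + n - 1L
  rx <- sparse_range_sums(pfx, xa, xb)
  ry <- sparse_range_sums(pfy, ya, yb)
  num <- n * raw - rx$s * ry$s
  den2 <- (n * rx$s2 - rx$s^2) * (n * ry$s2 - ry$s^2)
  out <- ifelse(den2 > 0 & n > 1, num / sqrt(pmax(den2, 0)), 0)
  out[!is.finite(out)] <- 0
  out
}

#' Gaussian smoothing of a correlation function
#'
#' Convolves the correlation values with a unit-area Gaussian kernel of
#' standard deviation `sigma` ms, truncated at +/- 4 sigma, to remove
#' high-frequency structure before peak detection. A kernel narrower than
#' one lag-grid step degenerates to the identity. The lag grid is
#' unchanged; total mass is preserved up to edge truncation.
#'
#' @param corr a [correlation_function()].
#' @param sigma kernel standard deviation in ms (>= 0).
#' @return a smoothed [correlation_function()].
#' @export
smooth_correlation <- function(corr, sigma) {
  stopifnot(inherits(corr, "correlation_function"), sigma >= 0)
  corr$values <- smooth_values(corr$values, corr$dt_ms, sigma)
  corr
}

smooth_values <- function(values, dt, sigma) {
  kern <- gauss_kernel(dt, sigma)
  if (length(kern) == 1) return(values)
  half <- (length(kern) - 1L) %/% 2L
  n <- length(values)
  # edge-replication padding: constants stay constant, interior mass is
  # preserved exactly by the unit-area kernel
  padded <- c(rep(values[1], half), values, rep(values[n], half))
  out <- convolve(padded, kern, type = "filter")
  stopifnot(length(out) == n)
  out
}

# unit-area Gaussian kernel on the lag grid, truncated at +/- 4 sigma;
# degenerates to identity when narrower than one sample
gauss_kernel <- function(dt, sigma) {
  if (sigma <= 0) return(1)
  half <- floor(4 * sigma / dt)
  if (half < 1) return(1)
  kern <- dnorm((-half:half) * dt, sd = sigma)
  kern / sum(kern)
}

#' Detect correlation peaks within a search window
#'
#' Finds local maxima of a (smoothed) correlation function inside the open
#' window `(-T, +T)` whose topographic prominence is at least
#' `min_prominence_frac` times the window dynamic range (global maximum in
#' the window minus the window baseline, i.e. its minimum). For each peak
#' the lag at the maximum (`tau_ms`), the value at the maximum
#' (`amplitude`), the prominence and the full width at half prominence
#' (`width_ms`, linearly interpolated on the lag grid) are returned. Peaks
#' at exactly zero lag are retained (they enter the triangle arithmetic)
#' but carry no direction and never become directed edges. Optional
#' absolute floors on amplitude and prominence discard peaks
#' indistinguishable from chance coincidences (callers derive them from
#' counting statistics).
#'
#' @param corr a [correlation_function()] (smooth it first).
#' @param T half-width of the search window in ms (> 0).
#' @param min_prominence_frac fraction in (0, 1] of the window dynamic
#'   range a peak's prominence must reach.
#' @param min_amplitude absolute amplitude floor (default 0 = off).
#' @param min_prominence_abs absolute prominence floor (default 0 = off);
#'   may also be a function of the peak amplitude.
#' @return data frame with columns `j`, `k`, `tau_ms`, `amplitude`,
#'   `prominence`, `width_ms`, `removed`, `removal_reason` (possibly 0
#'   rows).
#' @export
detect_peaks <- function(corr, T, min_prominence_frac = 0.2,
                         min_amplitude = 0, min_prominence_abs = 0) {
  stopifnot(inherits(corr, "correlation_function"), T > 0,
            min_prominence_frac > 0, min_prominence_frac <= 1)
  sel <- which(abs(corr$lags) < T)
  empty <- empty_peaks_df()
  if (length(sel) < 3) return(empty)
  v <- corr$values[sel]
  x <- corr$lags[sel]
  n <- length(v)
  baseline <- min(v)
  dyn <- max(v) - baseline
  if (dyn <= 0) return(empty)

  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(cand)) return(empty)

  nc <- length(cand)
  taus <- amps <- proms <- widths <- numeric(nc)
  keep <- logical(nc)
  for (ci in seq_len(nc)) {
    i <- cand[ci]
    vi <- v[i]
    # scan left/right to the next strictly higher sample (or window edge),
    # tracking the minimum; prominence = height above the higher saddle
    left_min <- vi; q <- i - 1L
    while (q >= 1 && v[q] <= vi) { left_min <- min(left_min, v[q]); q <- q - 1L }
    right_min <- vi; q <- i + 1L
    while (q <= n && v[q] <= vi) { right_min <- min(right_min, v[q]); q <- q + 1L }
    prom <- vi - max(left_min, right_min)
    prom_floor <- if (is.function(min_prominence_abs))
      min_prominence_abs(vi) else min_prominence_abs
    if (prom < min_prominence_frac * dyn || vi <= 0 || prom <= 0 ||
        vi < min_amplitude || prom < prom_floor) next
    level <- vi - prom / 2
    # full width at half prominence, linear interpolation on the grid
    q <- i; while (q > 1 && v[q - 1] >= level) q <- q - 1L
    lx <- if (q == 1) x[1] else
      x[q] - (x[q] - x[q - 1]) * (v[q] - level) / (v[q] - v[q - 1])
    q <- i; while (q < n && v[q + 1] >= level) q <- q + 1L
    rx <- if (q == n) x[n] else
      x[q] + (x[q + 1] - x[q]) * (v[q] - level) / (v[q] - v[q + 1])
    keep[ci] <- TRUE
    taus[ci] <- x[i]; amps[ci] <- vi; proms[ci] <- prom
    widths[ci] <- max(rx - lx, corr$dt_ms / 2)
  }
  if (!any(keep)) return(empty)
  data.frame(j = corr$pair[1], k = corr$pair[2], tau_ms = taus[keep],
             amplitude = amps[keep], prominence = proms[keep],
             width_ms = widths[keep], removed = FALSE, removal_reason = "",
             stringsAsFactors = FALSE)
}

#' Peak graph
#'
#' The set of surviving correlation peaks over all unordered neuron pairs
#' (stored once per pair with `j < k`; the reversed orientation is implied
#' by negating the lag). Carries the `(T, sigma)` parameters that produced
#' it.
#'
#' @param n_neurons neuron count.
#' @param peaks data frame as returned by [detect_peaks()].
#' @param T_ms,sigma_ms,dt_ms,mode producing parameters.
#' @return object of class `peak_graph`.
#' @export
peak_graph <- function(n_neurons, peaks, T_ms, sigma_ms,
                       dt_ms = NA_real_, mode = "raw") {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks)) {
    stopifnot(all(peaks$j < peaks$k), all(peaks$amplitude > 0))
    dup <- duplicated(peaks[, c("j", "k", "tau_ms")])
    peaks <- peaks[!dup, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  structure(list(n_neurons = n_neurons, peaks = peaks,
                 T_ms = T_ms, sigma_ms = sigma_ms,
                 dt_ms = dt_ms, mode = mode),
            class = "peak_graph")
}

#' @export
print.peak_graph <- function(x, ...) {
  cat(sprintf("peak_graph: %d neurons, %d peaks (%d surviving), T = %g ms, sigma = %g ms\n",
              x$n_neurons, nrow(x$peaks), sum(!x$peaks$removed),
              x$T_ms, x$sigma_ms))
  invisible(x)
}

#' Surviving peaks of a peak graph
#' @param pg a [peak_graph()].
#' @return data frame of peaks not marked removed.
#' @export
surviving_peaks <- function(pg) pg$peaks[!pg$peaks$removed, , drop = FALSE]

# ---- sparse correlogram machinery (pipeline fast path) ---------------------

# Raw correlograms for all unordered pairs j < k with >= 1 spike each,
# restricted to |lag| <= L bins. Returns list with pair index and counts.
pair_lag_counts <- function(trains, dt, L) {
  bins <- lapply(trains$spike_times, spike_bin_indices, dt = dt)
  active <- which(lengths(bins) > 0) - 1L
  out <- list()
  for (ji in seq_along(active)) {
    j <- active[ji]
    for (ki in seq_len(length(active) - ji)) {
      k <- active[ji + ki]
      out[[length(out) + 1L]] <- list(
        j = j, k = k,
        counts = .lag_histogram(bins[[j + 1L]], bins[[k + 1L]], L))
    }
  }
  out
}

# Peak detection for one pair from its extended raw correlogram: smooth,
# then detect within (-T, T) requiring each peak's prominence to be
# significant against counting noise — the smoothed count at a lag has
# approximate Poisson variance amplitude * sum(kernel^2), so the
# prominence floor is noise_z * sqrt(amplitude * sum(kernel^2)).
# Peak locations and widths always come from the raw count correlogram,
# where those counting statistics are exact. In "pearson" mode each
# detected peak's amplitude is then read off the smoothed
# Pearson-normalised correlogram at the peak lag: normalised amplitudes
# are insensitive to burst-driven mass inflation, which makes the
# minimum-amplitude rule of the triangle pruning robust on strongly
# bursting recordings.
peaks_from_counts <- function(counts, j, k, dt, L, T, sigma,
                              min_prominence_frac, noise_z, mode = "raw",
                              pearson_ctx = NULL) {
  lags <- (-L:L) * dt
  vals <- as.numeric(counts)
  # a pair whose near-window coincidence mass cannot reach significance is
  # skipped outright (prominence <= amplitude <= mass requires mass >= z^2 k2)
  if (noise_z > 0) {
    win <- abs(lags) <= T + 4 * sigma
    if (sum(vals[win]) < 8) return(empty_peaks_df())
  }
  vals <- smooth_values(vals, dt, sigma)
  prom_floor <- 0
  if (noise_z > 0) {
    k2 <- sum(gauss_kernel(dt, sigma)^2)
    prom_floor <- function(amp) noise_z * sqrt(pmax(amp, 1) * k2)
  }
  cf <- correlation_function(lags, vals, "raw", c(j, k), dt)
  pk <- detect_peaks(cf, T, min_prominence_frac,
                     min_prominence_abs = prom_floor)
  if (mode == "pearson" && !is.null(pearson_ctx) && nrow(pk)) {
    pv <- pearsonize(as.numeric(counts), -L:L, pearson_ctx$S,
                     pearson_ctx$pf[[j + 1L]], pearson_ctx$pf[[k + 1L]])
    pv <- smooth_values(pv, dt, sigma)
    idx <- match(as.integer(round(pk$tau_ms / dt)), -L:L)
    pk$amplitude <- pmax(pv[idx], 1e-12)
  }
  pk
}

#' Detect correlation peaks for all neuron pairs
#'
#' Runs the full correlation stage: bins the spike trains at `dt` ms,
#' computes the raw linear cross-correlogram of every unordered pair
#' `j < k` (neurons with zero spikes yield no peaks), smooths it with a
#' Gaussian kernel of standard deviation `sigma`, and detects peaks inside
#' `(-T, +T)`. Peaks must be statistically significant against counting
#' noise: the prominence must exceed `noise_z` standard deviations of the
#' smoothed count at the peak (Poisson statistics). Peak locations and
#' widths are always measured on the raw count correlogram; in `"pearson"`
#' mode each peak's amplitude is read off the smoothed Pearson-normalised
#' correlogram instead, which makes the downstream minimum-amplitude
#' pruning robust to burst-driven amplitude inflation. Set `noise_z = 0`
#' to disable the significance filter.
#'
#' @param trains a [spike_train_set()] with >= 2 active neurons.
#' @param dt bin width in ms (default 0.1, finer than all delay scales).
#' @param T peak-search half-window in ms.
#' @param sigma Gaussian smoothing sd in ms.
#' @param mode `"raw"` or `"pearson"`.
#' @param min_prominence_frac see [detect_peaks()].
#' @param noise_z prominence-significance multiplier (default 4).
#' @param flank_ms extension of the computed lag range beyond `T`
#'   (avoids smoothing edge effects and provides the Pearson-mode
#'   fluctuation estimate); default `max(2 * T, 10)`.
#' @return a [peak_graph()].
#' @export
all_pairwise_peaks <- function(trains, dt = 0.1, T, sigma,
                               mode = c("raw", "pearson"),
                               min_prominence_frac = 0.2,
                               noise_z = 4, flank_ms = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(trains, "spike_train_set"), T > 0, sigma >= 0, dt > 0)
  if (sum(lengths(trains$spike_times) > 0) < 2)
    stop("need at least 2 neurons with at least 1 spike")
  if (is.null(flank_ms)) flank_ms <- max(2 * T, 10)
  L <- as.integer(ceiling((T + 4 * sigma + flank_ms) / dt))
  pc <- pair_lag_counts(trains, dt, L)
  pctx <- if (mode == "pearson") pearson_context(trains, dt) else NULL
  res <- lapply(pc, function(p)
    peaks_from_counts(p$counts, p$j, p$k, dt, L, T, sigma,
                      min_prominence_frac, noise_z, mode, pctx))
  peak_graph(trains$n_neurons, bind_peaks(res), T, sigma, dt, mode)
}

# fast row-bind of many small peak data frames (identical columns)
bind_peaks <- function(dfs) {
  dfs <- dfs[vapply(dfs, nrow, integer(1)) > 0]
  if (!length(dfs)) return(empty_peaks_df())
  cols <- lapply(names(empty_peaks_df()), function(cn)
    unlist(lapply(dfs, `[[`, cn), use.names = FALSE))
  names(cols) <- names(empty_peaks_df())
  as.data.frame(cols, stringsAsFactors = FALSE)
}

.empty_peaks <- data.frame(
  j = integer(), k = integer(), tau_ms = numeric(),
  amplitude = numeric(), prominence = numeric(),
  width_ms = numeric(), removed = logical(),
  removal_reason = character(), stringsAsFactors = FALSE)

empty_peaks_df <- function() .empty_peaks

# sparse prefix sums of binned counts per neuron, for the per-lag Pearson
# normalisation without materialising dense signals
pearson_context <- function(trains, dt) {
  list(S = as.integer(ceiling(trains$duration * 1000 / dt)),
       pf = lapply(trains$spike_times, function(st)
         sparse_prefix(spike_bin_indices(st, dt))))
}

#' Suggested correlation-triangle threshold
#'
#' The triangle threshold epsilon is well approximated by the mean width of
#' the detected correlation peaks, which captures the variance of the
#' correlation delays.
#'
#' @param pg a [peak_graph()] with at least one surviving peak.
#' @return epsilon in ms.
#' @export
suggest_epsilon <- function(pg) {
  stopifnot(inherits(pg, "peak_graph"))
  sp <- surviving_peaks(pg)
  if (!nrow(sp)) stop("peak graph has no surviving peaks")
  mean(sp$width_ms)
}
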