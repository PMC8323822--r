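#' Build a (T, sigma) parameter grid
#'
#' Cartesian product of peak-search half-windows `T_values` and smoothing
#' widths `sigma_values` (both ms), sharing one triangle threshold
#' `epsilon`. The grid size `K = length(T_values) * length(sigma_values)`
#' is the denominator of the connection frequencies.
#'
#' @param T_values,sigma_values positive values in ms (non-empty).
#' @param epsilon triangle threshold in ms; may also be a vector of length
#'   `K` for per-point overrides.
#' @return data frame with columns `T`, `sigma`, `epsilon` (one row per
#'   point, deterministic order: `T` varies fastest).
#' @export
build_grid <- function(T_values, sigma_values, epsilon) {
  stopifnot(length(T_values) >= 1, length(sigma_values) >= 1,
            all(T_values > 0), all(sigma_values > 0), all(epsilon > 0))
  g <- expand.grid(T = T_values, sigma = sigma_values,
                   KEEP.OUT.ATTRS = FALSE)
  stopifnot(length(epsilon) %in% c(1L, nrow(g)))
  g$epsilon <- epsilon
  if (any(g$T <= g$epsilon))
    warning("grid contains points with T <= epsilon; ",
            "the search window is narrower than the triangle threshold")
  g
}

#' Shipped parameter profiles
#'
#' `"sim"`: the 9-point grid used to validate the method on simulated
#' sparse Izhikevich networks (`T` in 2.25, 3.5, 4.5 ms; `sigma` in 0.013,
#' 0.1, 0.63 ms; `epsilon` = 0.7 ms). `"mea"`: the grid for multi-electrode
#' array recordings of cultured neurons, whose synaptic latencies are an
#' order of magnitude longer (`T` in 16, 17.5, 20 ms; `sigma` in 0.4, 0.55,
#' 0.7 ms; `epsilon` = 3 ms).
#'
#' @param profile `"sim"` or `"mea"`.
#' @return a grid as from [build_grid()].
#' @export
default_grid <- function(profile = c("sim", "mea")) {
  profile <- match.arg(profile)
  if (profile == "sim")
    build_grid(c(2.25, 3.5, 4.5), c(0.013, 0.1, 0.63), 0.7)
  else
    build_grid(c(16, 17.5, 20), c(0.4, 0.55, 0.7), 3)
}

#' Frequency matrix
#'
#' Elementwise mean of the per-point binary connectivity matrices: entry
#' `f_jk` is the fraction of grid points asserting the directed edge
#' `j -> k` (a multiple of `1/K`, zero diagonal).
#'
#' @param values numeric matrix of frequencies.
#' @param K number of grid points combined.
#' @return object of class `frequency_matrix`.
#' @export
frequency_matrix <- function(values, K) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            all(values >= 0), all(values <= 1), all(diag(values) == 0))
  structure(list(values = values, K = K, n_neurons = nrow(values)),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("frequency_matrix: %d neurons, K = %d grid points, %d pairs with f > 0\n",
              x$n_neurons, x$K, sum(x$values > 0)))
  invisible(x)
}

#' Full super-selective reconstruction across a parameter grid
#'
#' For each grid point `(T, sigma, epsilon)`: detect all pairwise
#' correlation peaks, prune them by the super-selection rule and convert
#' the survivors into a binary connectivity matrix. The per-point matrices
#' are averaged into the connection frequency matrix. Raw correlograms are
#' computed once per pair on the widest lag range needed and reused across
#' grid points (they do not depend on `T` or `sigma`); this equals running
#' [all_pairwise_peaks()] independently per point. A point at which no
#' peaks survive contributes an all-zero matrix.
#'
#' @param trains a [spike_train_set()] with >= 2 active neurons.
#' @param grid data frame from [build_grid()] / [default_grid()].
#' @param dt correlogram bin width in ms.
#' @param mode `"pearson"` (default; peak amplitudes for the
#'   super-selection are read off the Pearson-normalised correlogram,
#'   recommended for spontaneously bursting recordings) or `"raw"`
#'   (amplitudes are the smoothed correlogram counts).
#' @param min_prominence_frac,noise_z,flank_ms see [all_pairwise_peaks()].
#' @param keep_matrices keep the per-point matrices (audit) in the result.
#' @return list with `freq` (a [frequency_matrix()]), `matrices` (list of
#'   per-point binary matrices, if kept) and `grid`.
#' @export
reconstruct <- function(trains, grid = default_grid("sim"), dt = 0.1,
                        mode = c("pearson", "raw"),
                        min_prominence_frac = 0.2, noise_z = 4,
                        flank_ms = NULL, keep_matrices = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(trains, "spike_train_set"))
  if (sum(lengths(trains$spike_times) > 0) < 2)
    stop("need at least 2 neurons with at least 1 spike")
  n <- trains$n_neurons
  T_max <- max(grid$T)
  if (is.null(flank_ms)) flank_ms <- max(2 * T_max, 10)
  L <- as.integer(ceiling((T_max + 4 * max(grid$sigma) + flank_ms) / dt))
  pc <- pair_lag_counts(trains, dt, L)
  pctx <- if (mode == "pearson") pearson_context(trains, dt) else NULL

  mats <- vector("list", nrow(grid))
  for (p in seq_len(nrow(grid))) {
    Tp <- grid$T[p]; sg <- grid$sigma[p]; eps <- grid$epsilon[p]
    res <- lapply(pc, function(pp)
      peaks_from_counts(pp$counts, pp$j, pp$k, dt, L, Tp, sg,
                        min_prominence_frac, noise_z, mode, pctx))
    pg <- peak_graph(n, bind_peaks(res), Tp, sg, dt, mode)
    pg <- prune_peaks(pg, eps)
    mats[[p]] <- peaks_to_matrix(pg)
  }
  f <- Reduce(`+`, mats) / nrow(grid)
  list(freq = frequency_matrix(f, nrow(grid)),
       matrices = if (keep_matrices) mats else NULL,
       grid = grid)
}

#' Threshold a frequency matrix at discrimination level d
#'
#' An edge survives iff its frequency reaches the discrimination threshold
#' `d`: `f_jk >= d` for `d > 0`; `d = 0` returns every edge asserted by at
#' least one grid point; `d = 1` requires unanimity across points. Because
#' true connections are re-detected by nearly all points (`f ~ 1`) while
#' false positives fluctuate from point to point, raising `d` suppresses
#' false positives while keeping the true-positive count nearly constant.
#'
#' @param freq a [frequency_matrix()].
#' @param d threshold in `[0, 1]`.
#' @return binary connectivity matrix.
#' @export
threshold_frequency <- function(freq, d) {
  stopifnot(inherits(freq, "frequency_matrix"), d >= 0, d <= 1)
  f <- freq$values
  m <- if (d == 0) (f > 0) else (f >= d)
  mode(m) <- "integer"
  diag(m) <- 0L
  m
}
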