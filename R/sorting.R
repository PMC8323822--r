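#' Waveform snippet set
#'
#' Spike waveform snippets recorded on one electrode: a matrix with one row
#' per detected event and one column per sample, plus the event times.
#'
#' @param snippets numeric matrix (events x samples).
#' @param event_times event times in seconds, sorted, one per row.
#' @param sample_interval_ms sampling interval of the snippets in ms.
#' @return object of class `waveform_set`.
#' @export
waveform_set <- function(snippets, event_times, sample_interval_ms = 0.05) {
  snippets <- as.matrix(snippets)
  stopifnot(nrow(snippets) == length(event_times),
            !is.unsorted(event_times))
  structure(list(snippets = snippets, event_times = as.numeric(event_times),
                 sample_interval_ms = sample_interval_ms),
            class = "waveform_set")
}

#' PCA features of spike waveforms
#'
#' Mean-centred principal component analysis of the snippets, retaining the
#' smallest number of components whose cumulative explained variance
#' reaches `variance_target`.
#'
#' @param waveforms a [waveform_set()] with >= 2 events.
#' @param variance_target cumulative explained-variance target in (0, 1].
#' @return list with `features` (events x retained components),
#'   `explained_variance` (per-component fractions) and `n_components`.
#' @export
pca_features <- function(waveforms, variance_target = 0.9) {
  stopifnot(inherits(waveforms, "waveform_set"),
            variance_target > 0, variance_target <= 1)
  x <- waveforms$snippets
  if (nrow(x) < 2) stop("need at least 2 events")
  if (all(apply(x, 2, var) == 0))
    stop("constant snippets: zero variance, nothing to extract")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  n_comp <- which(cumsum(ev) >= variance_target - 1e-12)[1]
  list(features = p$x[, seq_len(n_comp), drop = FALSE],
       explained_variance = ev, n_components = n_comp)
}

#' Cluster spike waveforms into putative units
#'
#' Replicated k-means over PCA features with automatic selection of the
#' number of units. Candidate `k` ranges from 1 to
#' `n_components + 1` (the PCA bound: `q` separable templates span about
#' `q - 1` leading components). For each `k`, k-means is restarted
#' `replicates` times and the solution with the lowest within-cluster sum
#' of point-to-centroid distances is kept. The final `k` is the elbow of
#' the within-cluster-sum curve (largest second difference), with a
#' fall-back to `k = 1` when even the best two-way split leaves more than
#' half of the total dispersion unexplained. Events farther than 3 times
#' their cluster's rms point-to-centroid distance are flagged as outliers
#' (never dropped).
#'
#' @param features matrix from [pca_features()] (or any finite feature
#'   matrix).
#' @param replicates random restarts per candidate `k` (default 20).
#' @param k_init smallest multi-cluster candidate (default 2).
#' @param k fixed number of units, overriding the automatic choice.
#' @param k_max largest candidate `k`; default `ncol(features) + 1`.
#' @param seed integer RNG seed (results deterministic given seed).
#' @return object of class `sort_result`: `labels` (0-based unit per
#'   event), `k`, `within_cluster_ss`, `wcss_curve`, `outlier` flags.
#' @export
sort_spikes <- function(features, replicates = 20, k_init = 2, k = NULL,
                        k_max = NULL, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(all(is.finite(features)), replicates >= 1, k_init >= 2)
  n <- nrow(features)
  if (is.null(k_max)) k_max <- ncol(features) + 1L
  # stats::kmeans needs strictly fewer centres than points
  k_cap <- max(1L, n - 1L)
  k_max <- min(max(k_init, k_max), k_cap)
  set.seed(seed)

  fit_k <- function(kk) {
    if (kk == 1) {
      ctr <- matrix(colMeans(features), 1)
      list(cluster = rep(1L, n), centers = ctr,
           tot.withinss = sum(scale(features, scale = FALSE)^2))
    } else {
      kmeans(features, centers = kk, nstart = replicates, iter.max = 100)
    }
  }

  if (!is.null(k)) {
    k_use <- min(k, k_cap)
    fit <- fit_k(k_use)
  } else {
    cands <- 1:k_max
    fits <- lapply(cands, fit_k)
    wcss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
    if (k_max == 1) {
      k_use <- 1L
    } else if (wcss[2] >= 0.5 * wcss[1]) {
      k_use <- 1L # best split explains too little: one unit
    } else if (k_max == 2) {
      k_use <- 2L
    } else {
      d2 <- wcss[1:(k_max - 2)] - 2 * wcss[2:(k_max - 1)] + wcss[3:k_max]
      k_use <- which.max(d2) + 1L
    }
    fit <- fits[[k_use]]
    attr(fit, "wcss_curve") <- wcss
  }

  centers <- fit$centers
  dists <- sqrt(rowSums((features - centers[fit$cluster, , drop = FALSE])^2))
  rms <- sqrt(tapply(dists^2, fit$cluster, mean))
  outlier <- dists > 3 * rms[as.character(fit$cluster)]
  structure(list(labels = fit$cluster - 1L, k = as.integer(k_use),
                 within_cluster_ss = fit$tot.withinss,
                 wcss_curve = attr(fit, "wcss_curve"),
                 outlier = as.logical(outlier)),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("sort_result: k = %d units, wcss = %.3g, %d outliers\n",
              x$k, x$within_cluster_ss, sum(x$outlier)))
  invisible(x)
}

#' Split events into per-unit spike trains
#'
#' Partitions the event times of a waveform set by the sorted unit labels:
#' one spike train per unit; every event appears in exactly one train.
#'
#' @param waveforms a [waveform_set()].
#' @param result a [sort_spikes()] result with one label per event.
#' @param duration recording duration in seconds; defaults to just past the
#'   last event.
#' @return a [spike_train_set()] with `k` neurons.
#' @export
split_trains <- function(waveforms, result, duration = NULL) {
  stopifnot(inherits(waveforms, "waveform_set"),
            inherits(result, "sort_result"),
            length(result$labels) == length(waveforms$event_times))
  if (is.null(duration))
    duration <- max(waveforms$event_times) * (1 + 1e-9) + 1e-9
  st <- lapply(0:(result$k - 1L), function(u)
    sort(waveforms$event_times[result$labels == u]))
  spike_train_set(st, duration)
}

#' Synthetic waveform fixture generator
#'
#' Builds a waveform set by drawing events from `nrow(templates)` units in
#' round-robin order and adding i.i.d. Gaussian noise — a synthetic
#' fixture for exercising and validating the spike sorter at known ground
#' truth.
#'
#' @param templates matrix (units x samples) of mean waveforms; default two
#'   biphasic shapes of opposite dominant polarity.
#' @param n_events total number of events.
#' @param noise_sd noise standard deviation (same units as templates).
#' @param seed integer RNG seed.
#' @return list with `waveforms` (a [waveform_set()]) and `labels` (true
#'   0-based unit of each event).
#' @export
generate_waveforms <- function(templates = NULL, n_events = 200,
                               noise_sd = 1, seed = 1L) {
  set.seed(seed)
  if (is.null(templates)) {
    s <- seq(0, 1, length.out = 32)
    templates <- rbind(
      -40 * exp(-((s - 0.3) / 0.08)^2) + 15 * exp(-((s - 0.55) / 0.15)^2),
      -15 * exp(-((s - 0.35) / 0.12)^2) + 30 * exp(-((s - 0.6) / 0.1)^2))
  }
  templates <- as.matrix(templates)
  labels <- rep_len(0:(nrow(templates) - 1L), n_events)
  snip <- templates[labels + 1L, , drop = FALSE] +
    matrix(rnorm(n_events * ncol(templates), 0, noise_sd),
           n_events, ncol(templates))
  times <- sort(runif(n_events, 0, n_events / 10))
  list(waveforms = waveform_set(snip, times), labels = labels)
}
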