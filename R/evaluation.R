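#' Score a reconstruction against ground truth
#'
#' Confusion counts over all ordered off-diagonal pairs, plus the derived
#' indicators: `tp_rate = TP / n_c`, `fp_rate = FP / n_c`, the confidence
#' indicator `delta = (TP - FP) / n_c` (independent of network density) and
#' the accuracy `acc = (TP + TN) / n_tot` with `n_tot = n (n - 1)`. Note
#' that for sparse truth the accuracy is dominated by true negatives and
#' overstates performance, especially for large networks.
#'
#' @param predicted binary connectivity matrix.
#' @param truth a [network_model()] or a binary matrix of the same size.
#' @return object of class `evaluation_result` (a list with fields `TP`,
#'   `FP`, `TN`, `FN`, `n_c`, `n_tot`, `tp_rate`, `fp_rate`, `delta`,
#'   `acc`).
#' @export
score <- function(predicted, truth) {
  tm <- if (inherits(truth, "network_model")) truth_matrix(truth) else truth
  stopifnot(is.matrix(predicted), is.matrix(tm),
            all(dim(predicted) == dim(tm)))
  n <- nrow(tm)
  off <- row(tm) != col(tm)
  p <- predicted[off] != 0
  t <- tm[off] != 0
  n_c <- sum(t)
  if (n_c == 0) stop("ground truth has no edges; delta undefined")
  TP <- sum(p & t); FP <- sum(p & !t)
  FN <- sum(!p & t); TN <- sum(!p & !t)
  n_tot <- n * (n - 1)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 n_c = n_c, n_tot = n_tot,
                 tp_rate = TP / n_c, fp_rate = FP / n_c,
                 delta = (TP - FP) / n_c, acc = (TP + TN) / n_tot),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "evaluation_result: TP %d/%d  FP %d  delta %.3f  acc %.3f\n",
    x$TP, x$n_c, x$FP, x$delta, x$acc))
  invisible(x)
}

#' Degree-based node metrics and hub detection
#'
#' In- and out-degrees from a directed binary matrix, the in-degree
#' fraction `in / (in + out)` (NA for isolated nodes), and hub flags. Hubs
#' are the top in-degree-ranked nodes; by default a node is a hub when its
#' in-degree strictly exceeds `mean + hub_z * sd` of the in-degrees
#' (`hub_rule = "zscore"`); alternatively the top `1 - hub_percentile`
#' fraction of nodes by in-degree (`hub_rule = "percentile"`).
#'
#' @param matrix binary connectivity matrix.
#' @param hub_rule `"zscore"` or `"percentile"`.
#' @param hub_z z-score threshold (default 2).
#' @param hub_percentile percentile cut for the alternative rule
#'   (default 0.95).
#' @return list with `nodes` (data frame: `id`, `in_degree`, `out_degree`,
#'   `in_degree_fraction`, `hub`), `n_hubs` and `max_hub_size` (largest hub
#'   in-degree, 0 if no hubs).
#' @export
degree_metrics <- function(matrix, hub_rule = c("zscore", "percentile"),
                           hub_z = 2, hub_percentile = 0.95) {
  hub_rule <- match.arg(hub_rule)
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  n <- nrow(matrix)
  m <- matrix != 0
  diag(m) <- FALSE
  in_deg <- colSums(m)
  out_deg <- rowSums(m)
  tot <- in_deg + out_deg
  frac <- ifelse(tot > 0, in_deg / tot, NA_real_)
  hub <- if (hub_rule == "zscore") {
    thr <- mean(in_deg) + hub_z * sd(in_deg)
    in_deg > thr & in_deg > 0
  } else {
    thr <- stats::quantile(in_deg, hub_percentile, type = 1)
    in_deg > thr & in_deg > 0
  }
  list(nodes = data.frame(id = 0:(n - 1), in_degree = in_deg,
                          out_degree = out_deg,
                          in_degree_fraction = frac, hub = hub),
       n_hubs = sum(hub),
       max_hub_size = if (any(hub)) max(in_deg[hub]) else 0)
}

#' Mean path length and mean clustering coefficient
#'
#' Mean shortest-path length over all ordered node pairs connected by a
#' finite directed path (unweighted; infinite/absent paths are excluded;
#' NA when no finite pair exists), and the node-averaged local clustering
#' coefficient of the undirected projection (fraction of a node's
#' neighbour pairs that are themselves connected; nodes of degree < 2
#' contribute 0).
#'
#' @param matrix binary connectivity matrix.
#' @return list with `mean_path_length` and `mean_clustering`.
#' @export
path_clustering <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  n <- nrow(matrix)
  g <- igraph::graph_from_adjacency_matrix(matrix != 0, mode = "directed")
  d <- igraph::distances(g, mode = "out")
  d <- d[row(d) != col(d)]
  finite <- is.finite(d)
  mpl <- if (any(finite)) mean(d[finite]) else NA_real_
  gu <- igraph::as_undirected(g, mode = "collapse")
  cc <- igraph::transitivity(gu, type = "local", isolates = "zero")
  cc[igraph::degree(gu) < 2] <- 0
  list(mean_path_length = mpl, mean_clustering = mean(cc))
}

#' Receiver-probability estimate from spike timing
#'
#' For each neuron `j`, counts the spikes of all other neurons falling
#' within `window` ms before (`s_minus`, interval `[t - w, t)`) or after
#' (`s_plus`, interval `(t, t + w]`) each spike `t` of neuron `j`; exactly
#' simultaneous spikes count on neither side. The ratio
#' `s_minus / (s_plus + s_minus)` estimates the probability that the
#' neuron is a receiver: values near 1 mark receivers, near 0 initiators,
#' intermediate values propagators. Neurons with no spikes in any window
#' report a missing probability.
#'
#' @param trains a [spike_train_set()].
#' @param window half-window in ms (default 15).
#' @return data frame with columns `id`, `s_plus`, `s_minus`,
#'   `receiver_prob`.
#' @export
receiver_probability <- function(trains, window = 15) {
  stopifnot(inherits(trains, "spike_train_set"), window > 0)
  w <- window / 1000
  n <- trains$n_neurons
  out <- data.frame(id = 0:(n - 1), s_plus = 0L, s_minus = 0L,
                    receiver_prob = NA_real_)
  for (j in seq_len(n)) {
    tj <- trains$spike_times[[j]]
    if (!length(tj)) next
    others <- sort(unlist(trains$spike_times[-j], use.names = FALSE))
    if (!length(others)) next
    # counts in [t - w, t): spikes < t minus spikes < t - w
    s_minus <- sum(findInterval(tj, others, left.open = TRUE) -
                   findInterval(tj - w, others, left.open = TRUE))
    # counts in (t, t + w]: spikes <= t + w minus spikes <= t
    s_plus <- sum(findInterval(tj + w, others) - findInterval(tj, others))
    out$s_plus[j] <- s_plus
    out$s_minus[j] <- s_minus
    if (s_plus + s_minus > 0)
      out$receiver_prob[j] <- s_minus / (s_plus + s_minus)
  }
  attr(out, "window_ms") <- window
  out
}

#' Regress in-degree fraction on receiver probability
#'
#' Ordinary least squares of the reconstructed in-degree fraction on the
#' timing-based receiver-probability estimate, over neurons for which both
#' are defined. A strong linear relation indicates that the inferred
#' directionality agrees with the raw spike-timing asymmetry.
#'
#' @param est data frame from [receiver_probability()].
#' @param metrics list from [degree_metrics()].
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
receiver_vs_indegree <- function(est, metrics) {
  df <- merge(est, metrics$nodes, by = "id")
  df <- df[is.finite(df$receiver_prob) & is.finite(df$in_degree_fraction), ]
  if (nrow(df) < 3)
    stop("need at least 3 neurons with both quantities defined")
  if (var(df$receiver_prob) == 0)
    stop("receiver probability is constant; regression degenerate")
  fit <- lm(in_degree_fraction ~ receiver_prob, data = df)
  tss <- sum((df$in_degree_fraction - mean(df$in_degree_fraction))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = nrow(df))
}
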