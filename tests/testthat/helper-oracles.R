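# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# direct O(S^2) linear cross-correlation: sum_t x(t) y(t + lag)
brute_xcorr <- function(x, y, max_lag) {
  S <- length(x)
  sapply(-max_lag:max_lag, function(l) {
    s <- 0
    for (t in seq_len(S)) {
      u <- t + l
      if (u >= 1 && u <= S) s <- s + x[t] * y[u]
    }
    s
  })
}

# exhaustive enumeration of flagged cyclic triangles from a peak table
# (columns j, k, tau_ms, amplitude; j < k), independent of enumerate_triangles
brute_flagged_triangles <- function(peaks, epsilon) {
  n <- max(peaks$j, peaks$k) + 1L
  out <- list()
  for (j in 0:(n - 3)) for (k in (j + 1):(n - 2)) for (m in (k + 1):(n - 1)) {
    p_jk <- which(peaks$j == j & peaks$k == k)
    p_km <- which(peaks$j == k & peaks$k == m)
    p_jm <- which(peaks$j == j & peaks$k == m)
    for (a in p_jk) for (b in p_km) for (cc in p_jm) {
      cl <- abs(peaks$tau_ms[a] + peaks$tau_ms[b] - peaks$tau_ms[cc])
      if (cl < epsilon)
        out[[length(out) + 1L]] <- c(a, b, cc)
    }
  }
  out
}

# pair-by-pair confusion counting
brute_score <- function(pred, truth) {
  n <- nrow(truth)
  TP <- FP <- TN <- FN <- 0
  for (j in 1:n) for (k in 1:n) {
    if (j == k) next
    p <- pred[j, k] != 0
    t <- truth[j, k] != 0
    if (p && t) TP <- TP + 1
    if (p && !t) FP <- FP + 1
    if (!p && t) FN <- FN + 1
    if (!p && !t) TN <- TN + 1
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN)
}

# all-pairs shortest directed paths by explicit BFS
brute_mean_path_length <- function(m) {
  n <- nrow(m)
  dists <- c()
  for (s in 1:n) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(m[v, ] != 0)) {
          if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
    dists <- c(dists, d[-s])
  }
  dists <- dists[is.finite(dists)]
  if (length(dists)) mean(dists) else NA_real_
}

# node-averaged undirected clustering coefficient by triangle counting
brute_mean_clustering <- function(m) {
  u <- (m | t(m)) * 1
  diag(u) <- 0
  n <- nrow(u)
  cc <- numeric(n)
  for (v in 1:n) {
    nb <- which(u[v, ] != 0)
    if (length(nb) < 2) { cc[v] <- 0; next }
    links <- 0
    for (a in nb) for (b in nb) if (a < b && u[a, b] != 0) links <- links + 1
    cc[v] <- links / choose(length(nb), 2)
  }
  mean(cc)
}

# build a peak_graph directly from a table of implied directed links
# (src, dst, tau > 0 means src leads dst), for superselection unit tests
peaks_from_table <- function(n, j, k, tau, amp, width = 1) {
  df <- data.frame(j = j, k = k, tau_ms = tau, amplitude = amp,
                   prominence = amp, width_ms = width,
                   removed = FALSE, removal_reason = "",
                   stringsAsFactors = FALSE)
  peak_graph(n, df, T_ms = 10, sigma_ms = 0.1)
}

# binned signal helper
sig <- function(values, dt = 1) {
  structure(list(values = values, dt_ms = dt, n_samples = length(values)),
            class = "spike_signal")
}
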