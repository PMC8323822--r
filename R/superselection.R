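#' Enumerate cyclic correlation triangles
#'
#' For every unordered neuron triplet `{j, k, m}` (with `j < k < m`) whose
#' three pairs each hold at least one surviving correlation peak, emits one
#' triangle per combination of one peak per pair, oriented cyclically
#' `j -> k -> m -> j`. Peaks are stored once per pair with `j < k`; when a
#' pair enters the cycle in reversed orientation its delay enters with
#' negated sign (the reversed peak of a correlogram sits at the mirrored
#' lag). The `closure` of a triangle is `|tau_jk + tau_km + tau_mj|`: a
#' near-zero closure means one of the three delays is the combination of
#' the other two, i.e. one peak reflects an indirect or apparent link.
#'
#' @param pg a [peak_graph()].
#' @return data frame with one row per triangle: neuron ids `j, k, m`,
#'   oriented delays `tau_jk, tau_km, tau_mj`, amplitudes
#'   `a_jk, a_km, a_mj`, peak row ids `pid_jk, pid_km, pid_mj` (row numbers
#'   in `pg$peaks`), `closure` (ms) and `flagged` (set by
#'   [flag_triangles()]).
#' @export
enumerate_triangles <- function(pg) {
  stopifnot(inherits(pg, "peak_graph"))
  pk <- pg$peaks
  alive <- which(!pk$removed)
  empty <- data.frame(j = integer(), k = integer(), m = integer(),
                      tau_jk = numeric(), tau_km = numeric(),
                      tau_mj = numeric(), a_jk = numeric(),
                      a_km = numeric(), a_mj = numeric(),
                      pid_jk = integer(), pid_km = integer(),
                      pid_mj = integer(), closure = numeric(),
                      flagged = logical())
  if (length(alive) < 3) return(empty)
  n <- pg$n_neurons
  key <- function(a, b) a * n + b # a < b
  by_pair <- split(alive, key(pk$j[alive], pk$k[alive]))
  pairs <- unique(pk[alive, c("j", "k")])
  has <- matrix(FALSE, n, n)
  has[cbind(pairs$j + 1L, pairs$k + 1L)] <- TRUE

  acc1 <- list(); acc2 <- list(); acc3 <- list()
  accj <- list(); acck <- list(); accm <- list()
  nacc <- 0L
  for (r in seq_len(nrow(pairs))) {
    j <- pairs$j[r]; k <- pairs$k[r]
    ms <- which(has[j + 1L, ] & has[k + 1L, ]) - 1L
    ms <- ms[ms > k]
    p_jk <- by_pair[[as.character(key(j, k))]]
    n1 <- length(p_jk)
    for (m in ms) {
      p_km <- by_pair[[as.character(key(k, m))]]
      p_jm <- by_pair[[as.character(key(j, m))]]
      n2 <- length(p_km); n3 <- length(p_jm)
      nacc <- nacc + 1L
      # all combinations of one peak per pair (column-major expansion)
      acc1[[nacc]] <- rep.int(p_jk, n2 * n3)
      acc2[[nacc]] <- rep.int(rep(p_km, each = n1), n3)
      acc3[[nacc]] <- rep(p_jm, each = n1 * n2)
      accj[[nacc]] <- rep.int(j, n1 * n2 * n3)
      acck[[nacc]] <- rep.int(k, n1 * n2 * n3)
      accm[[nacc]] <- rep.int(m, n1 * n2 * n3)
    }
  }
  if (!nacc) return(empty)
  pid_jk <- unlist(acc1, use.names = FALSE)
  pid_km <- unlist(acc2, use.names = FALSE)
  pid_mj <- unlist(acc3, use.names = FALSE)
  # cyclic orientation j -> k -> m -> j: the (j, m) peak enters as the
  # reversed pair (m, j), hence with negated delay
  tri <- data.frame(
    j = unlist(accj, use.names = FALSE),
    k = unlist(acck, use.names = FALSE),
    m = unlist(accm, use.names = FALSE),
    tau_jk = pk$tau_ms[pid_jk],
    tau_km = pk$tau_ms[pid_km],
    tau_mj = -pk$tau_ms[pid_mj],
    a_jk = pk$amplitude[pid_jk],
    a_km = pk$amplitude[pid_km],
    a_mj = pk$amplitude[pid_mj],
    pid_jk = pid_jk, pid_km = pid_km, pid_mj = pid_mj)
  tri$closure <- abs(tri$tau_jk + tri$tau_km + tri$tau_mj)
  tri$flagged <- FALSE
  tri
}

#' Flag triangles whose delays nearly cancel
#'
#' A triangle is flagged when its closure `|tau_jk + tau_km + tau_mj|` is
#' strictly below the threshold `epsilon`: the three delays are then the
#' combination of one another, so one of the three peaks represents an
#' indirect or apparent link.
#'
#' @param triangles data frame from [enumerate_triangles()].
#' @param epsilon triangle threshold in ms (> 0).
#' @return the data frame with `flagged` updated.
#' @export
flag_triangles <- function(triangles, epsilon) {
  stopifnot(epsilon > 0)
  triangles$flagged <- triangles$closure < epsilon
  triangles
}

#' Super-selection pruning of indirect and apparent peaks
#'
#' Applies the super-selection rule: in each flagged triangle the peak of
#' minimum amplitude estimates the false-positive link and is discarded.
#' Flagged triangles are processed in ascending closure order (ties broken
#' by lexicographic neuron indices); a triangle is skipped if any of its
#' three peaks was already removed. After a full pass, triangles are
#' re-enumerated from the survivors and the procedure repeats until a pass
#' removes nothing (fixed point). Amplitude ties fall to the widest peak,
#' then the largest |tau|, then the lexicographically last pair. Removed
#' peaks stay in the graph, marked with reason `"triangle"` (audit trail);
#' no peak is ever added.
#'
#' @param pg a [peak_graph()].
#' @param epsilon triangle threshold in ms (> 0).
#' @param max_passes maximum number of removal passes (default `Inf`:
#'   iterate to the fixed point).
#' @return the pruned [peak_graph()].
#' @export
prune_peaks <- function(pg, epsilon, max_passes = Inf) {
  stopifnot(inherits(pg, "peak_graph"), epsilon > 0, max_passes >= 1)
  pk <- pg$peaks
  if (!nrow(pk)) return(pg)
  removed <- pk$removed
  pass <- 0
  repeat {
    pass <- pass + 1
    if (pass > max_passes) break
    pg$peaks$removed <- removed
    tri <- flag_triangles(enumerate_triangles(pg), epsilon)
    tri <- tri[tri$flagged, , drop = FALSE]
    if (!nrow(tri)) break
    tri <- tri[order(tri$closure, tri$j, tri$k, tri$m,
                     tri$tau_jk, tri$tau_km, tri$tau_mj), , drop = FALSE]
    any_removed <- FALSE
    for (r in seq_len(nrow(tri))) {
      pids <- c(tri$pid_jk[r], tri$pid_km[r], tri$pid_mj[r])
      if (any(removed[pids])) next
      amps <- c(tri$a_jk[r], tri$a_km[r], tri$a_mj[r])
      victim <- pick_victim(pids, amps, pk)
      removed[victim] <- TRUE
      any_removed <- TRUE
    }
    if (!any_removed) break
  }
  pg$peaks$removed <- removed
  pg$peaks$removal_reason[removed & pg$peaks$removal_reason == ""] <- "triangle"
  pg
}

# choose the peak to discard among a triangle's three peaks:
# min amplitude; ties -> largest width, then largest |tau|, then
# lexicographically last stored pair (j, k)
pick_victim <- function(pids, amps, pk) {
  cand <- which(amps == min(amps))
  if (length(cand) > 1) {
    w <- pk$width_ms[pids[cand]]
    cand <- cand[w == max(w)]
  }
  if (length(cand) > 1) {
    at <- abs(pk$tau_ms[pids[cand]])
    cand <- cand[at == max(at)]
  }
  if (length(cand) > 1) {
    ord <- order(pk$j[pids[cand]], pk$k[pids[cand]], pk$tau_ms[pids[cand]])
    cand <- cand[ord[length(ord)]]
  }
  pids[cand[1]]
}

#' Directed connectivity matrix from surviving peaks
#'
#' Entry `(j, k)` is 1 iff some surviving peak implies a positive delay
#' from `j` to `k`: a stored `(j, k)` peak with `tau > 0`, or a stored
#' `(k, j)` peak with `tau < 0` (mirror orientation). Zero-lag peaks carry
#' no direction and contribute nothing; the diagonal is zero.
#'
#' @param pg a [peak_graph()] (pruned or not).
#' @return binary `n x n` matrix.
#' @export
peaks_to_matrix <- function(pg) {
  stopifnot(inherits(pg, "peak_graph"))
  n <- pg$n_neurons
  m <- matrix(0L, n, n)
  sp <- surviving_peaks(pg)
  if (nrow(sp)) {
    pos <- sp[sp$tau_ms > 0, , drop = FALSE]
    neg <- sp[sp$tau_ms < 0, , drop = FALSE]
    if (nrow(pos)) m[cbind(pos$j + 1L, pos$k + 1L)] <- 1L
    if (nrow(neg)) m[cbind(neg$k + 1L, neg$j + 1L)] <- 1L
  }
  m
}
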