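test_that("triangle enumeration counts all peak combinations once", {
  # 3 neurons, 2 peaks per pair -> 2^3 = 8 triangles
  pg8 <- peaks_from_table(3,
    j = c(0, 0, 1, 1, 0, 0), k = c(1, 1, 2, 2, 2, 2),
    tau = c(1, -2, 1.5, -1, 2.5, -3), amp = 1:6)
  tri <- enumerate_triangles(pg8)
  expect_equal(nrow(tri), 8)
  expect_false(any(duplicated(tri[, c("pid_jk", "pid_km", "pid_mj")])))

  # 1 peak per pair -> a single triangle
  pg1 <- peaks_from_table(3, j = c(0, 1, 0), k = c(1, 2, 2),
                          tau = c(2, 3, 5), amp = c(3, 3, 1))
  expect_equal(nrow(enumerate_triangles(pg1)), 1)

  # 4 fully connected neurons, 1 peak per pair -> C(4,3) = 4 triangles
  cmb <- t(combn(0:3, 2))
  pg4 <- peaks_from_table(4, j = cmb[, 1], k = cmb[, 2],
                          tau = seq(1, 6), amp = rep(2, 6))
  tri4 <- enumerate_triangles(pg4)
  expect_equal(nrow(tri4), 4)
  expect_equal(nrow(unique(tri4[, c("j", "k", "m")])), 4)
})

test_that("reversed pairs enter triangles with negated delays", {
  pg <- peaks_from_table(3, j = c(0, 1, 0), k = c(1, 2, 2),
                         tau = c(2, 3, 5), amp = c(3, 3, 1))
  tri <- enumerate_triangles(pg)
  expect_equal(tri$tau_jk, 2)
  expect_equal(tri$tau_km, 3)
  expect_equal(tri$tau_mj, -5)
  expect_equal(tri$closure, 0)
})

test_that("triangle flagging uses a strict closure threshold", {
  pg <- peaks_from_table(3, j = c(0, 1, 0), k = c(1, 2, 2),
                         tau = c(2, 3, 5), amp = c(3, 3, 1))
  tri <- enumerate_triangles(pg)
  expect_true(flag_triangles(tri, 0.5)$flagged)

  pg2 <- peaks_from_table(3, j = c(0, 1, 0), k = c(1, 2, 2),
                          tau = c(2, 3, 10), amp = c(3, 3, 1))
  tri2 <- enumerate_triangles(pg2) # closure 5
  expect_false(flag_triangles(tri2, 0.5)$flagged)
  # strict inequality: closure exactly epsilon is not flagged
  expect_false(flag_triangles(tri2, 5)$flagged)
  expect_true(flag_triangles(tri2, 5.0001)$flagged)
})

test_that("pruning removes the minimum-amplitude peak of a closing triangle", {
  # chain 0 -> 1 -> 2: indirect (0,2) correlation is weakest
  pg <- peaks_from_table(3, j = c(0, 1, 0), k = c(1, 2, 2),
                         tau = c(2, 3, 5), amp = c(10, 9, 4))
  out <- prune_peaks(pg, epsilon = 0.7)
  expect_equal(sum(out$peaks$removed), 1)
  rem <- out$peaks[out$peaks$removed, ]
  expect_equal(c(rem$j, rem$k), c(0, 2))
  expect_equal(rem$removal_reason, "triangle")
  m <- peaks_to_matrix(out)
  expect_equal(which(m == 1), c(4, 8)) # edges 0->1 and 1->2 (column-major)
})

test_that("pruning on jittered chain and common-input fixtures keeps true edges", {
  chain <- generate_delta_motif("chain", delays = c(2, 3), event_rate = 8,
                                jitter_sd = 0.4, duration = 240, seed = 5)
  pg <- all_pairwise_peaks(chain$trains, dt = 0.1, T = 8, sigma = 0.1)
  out <- prune_peaks(pg, 0.7)
  expect_equal(peaks_to_matrix(out), truth_matrix(chain$model))

  ci <- generate_delta_motif("common_input", delays = c(2, 4), event_rate = 8,
                             jitter_sd = 0.4, duration = 240, seed = 6)
  pg2 <- all_pairwise_peaks(ci$trains, dt = 0.1, T = 8, sigma = 0.1)
  # before pruning, the siblings (1,2) carry an apparent peak near +2 ms
  expect_true(any(pg2$peaks$j == 1 & pg2$peaks$k == 2))
  out2 <- prune_peaks(pg2, 0.7)
  expect_equal(peaks_to_matrix(out2), truth_matrix(ci$model))
})

test_that("pruning is conservative, deterministic and idempotent", {
  pg <- peaks_from_table(3, j = c(0, 1, 0), k = c(1, 2, 2),
                         tau = c(2, 3, 10), amp = c(3, 3, 1))
  out <- prune_peaks(pg, 0.7) # no closing triangle
  expect_identical(out$peaks, pg$peaks)

  set.seed(8)
  n <- 6
  cmb <- t(combn(0:(n - 1), 2))
  idx <- rep(seq_len(nrow(cmb)), each = 2)
  pg2 <- peaks_from_table(n, j = cmb[idx, 1], k = cmb[idx, 2],
                          tau = round(runif(2 * nrow(cmb), -5, 5), 1),
                          amp = round(runif(2 * nrow(cmb), 1, 10), 2),
                          width = round(runif(2 * nrow(cmb), 0.5, 2), 2))
  out2 <- prune_peaks(pg2, 1)
  expect_gt(sum(out2$peaks$removed), 0)
  # monotone reduction: pruned edges are a subset of unpruned edges
  expect_true(all(peaks_to_matrix(out2) <= peaks_to_matrix(pg2)))
  # idempotence
  expect_equal(prune_peaks(out2, 1)$peaks, out2$peaks)
  # determinism under input row permutation
  perm <- sample(nrow(pg2$peaks))
  pg2p <- peak_graph(n, pg2$peaks[perm, ], pg2$T_ms, pg2$sigma_ms)
  out2p <- prune_peaks(pg2p, 1)
  a <- out2$peaks[order(out2$peaks$j, out2$peaks$k, out2$peaks$tau_ms), ]
  b <- out2p$peaks[order(out2p$peaks$j, out2p$peaks$k, out2p$peaks$tau_ms), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("flagged triangles match an exhaustive enumeration oracle", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    cmb <- t(combn(0:(n - 1), 2))
    pick <- cmb[runif(nrow(cmb)) < 0.8, , drop = FALSE]
    idx <- rep(seq_len(nrow(pick)), sample(1:2, nrow(pick), replace = TRUE))
    pg <- peaks_from_table(n, j = pick[idx, 1], k = pick[idx, 2],
                           tau = round(runif(length(idx), -5, 5), 1),
                           amp = runif(length(idx), 1, 10))
    eps <- runif(1, 0.5, 2)
    tri <- flag_triangles(enumerate_triangles(pg), eps)
    got <- tri[tri$flagged, c("pid_jk", "pid_km", "pid_mj")]
    want <- brute_flagged_triangles(pg$peaks, eps)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      key <- function(m) unname(sort(apply(m, 1, paste, collapse = "-")))
      expect_equal(key(as.matrix(got)), key(do.call(rbind, want)))
    }
  }
})

test_that("amplitude ties fall to the widest peak", {
  pg <- peaks_from_table(3, j = c(0, 1, 0), k = c(1, 2, 2),
                         tau = c(2, 3, 5), amp = c(4, 4, 4),
                         width = c(1, 1, 2.5))
  out <- prune_peaks(pg, 0.7)
  rem <- out$peaks[out$peaks$removed, ]
  expect_equal(c(rem$j, rem$k), c(0, 2)) # the widest (indirect) peak
})

test_that("connectivity matrices follow the positive-delay convention", {
  pg <- peaks_from_table(4, j = c(1, 1, 2), k = c(2, 2, 3),
                         tau = c(1.5, -2, 1), amp = c(3, 3, 3))
  m <- peaks_to_matrix(pg)
  want <- matrix(0L, 4, 4)
  want[2, 3] <- 1L; want[3, 2] <- 1L; want[3, 4] <- 1L
  expect_equal(m, want)

  empty <- peak_graph(4, pg$peaks[0, ], 10, 0.1)
  expect_equal(peaks_to_matrix(empty), matrix(0L, 4, 4))

  # zero-lag peaks carry no direction
  pg0 <- peaks_from_table(3, j = 0, k = 1, tau = 0, amp = 2)
  expect_equal(sum(peaks_to_matrix(pg0)), 0)

  # random peak graphs match a per-pair sign oracle
  set.seed(10)
  for (rep in 1:3) {
    n <- 5
    cmb <- t(combn(0:(n - 1), 2))
    idx <- rep(seq_len(nrow(cmb)), sample(0:2, nrow(cmb), replace = TRUE))
    if (!length(idx)) next
    taus <- round(runif(length(idx), -3, 3), 1)
    pg <- peaks_from_table(n, cmb[idx, 1], cmb[idx, 2], taus,
                           amp = runif(length(idx), 1, 5))
    m <- peaks_to_matrix(pg)
    want <- matrix(0L, n, n)
    pk <- pg$peaks
    for (r in seq_len(nrow(pk))) {
      if (pk$tau_ms[r] > 0) want[pk$j[r] + 1, pk$k[r] + 1] <- 1L
      if (pk$tau_ms[r] < 0) want[pk$k[r] + 1, pk$j[r] + 1] <- 1L
    }
    expect_equal(m, want)
  }
})
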