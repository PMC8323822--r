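test_that("binning counts spikes into the right bins and conserves totals", {
  tr <- spike_train_set(list(c(1.0, 2.0)), duration = 3)
  s <- bin_spikes(tr, dt = 1)[[1]]
  expect_equal(s$n_samples, 3000)
  expect_equal(which(s$values == 1), c(1001, 2001))
  expect_equal(sum(s$values), 2)

  # two spikes in one bin
  tr2 <- spike_train_set(list(c(0.0101, 0.0104)), duration = 1)
  s2 <- bin_spikes(tr2, dt = 1)[[1]]
  expect_equal(max(s2$values), 2)

  # count conservation on random trains, all signals share n_samples
  set.seed(1)
  st <- lapply(1:4, function(i) sort(runif(sample(5:50, 1), 0, 10)))
  tr3 <- spike_train_set(st, duration = 10)
  sigs <- bin_spikes(tr3, dt = 0.5)
  expect_equal(sapply(sigs, function(s) sum(s$values)), lengths(st))
  expect_equal(length(unique(sapply(sigs, `[[`, "n_samples"))), 1L)
})

test_that("raw cross-correlation matches shift identities and the direct sum", {
  x <- c(0, 1, 0, 2, 0, 0, 1, 0)
  cf <- cross_correlation(sig(x), sig(x), mode = "raw")
  expect_equal(cf$values[cf$lags == 0], sum(x^2))
  expect_equal(cf$lags[which.max(cf$values)], 0)

  # s_k = s_j delayed by +5 samples -> maximum at +5 * dt
  set.seed(2)
  xj <- as.numeric(runif(300) < 0.1)
  xk <- c(rep(0, 5), xj[1:295])
  cf2 <- cross_correlation(sig(xj, dt = 0.5), sig(xk, dt = 0.5))
  expect_equal(cf2$lags[which.max(cf2$values)], 2.5)

  # FFT path equals the brute-force double sum on random sparse signals
  set.seed(3)
  a <- rpois(400, 0.2); b <- rpois(400, 0.2)
  cf3 <- cross_correlation(sig(a), sig(b), max_lag_ms = 50)
  expect_equal(cf3$values, brute_xcorr(a, b, 50), tolerance = 1e-10)
})

test_that("correlation obeys the reversal symmetry R_jk(tau) = R_kj(-tau)", {
  set.seed(4)
  a <- rpois(256, 0.3); b <- rpois(256, 0.3)
  ab <- cross_correlation(sig(a), sig(b))
  ba <- cross_correlation(sig(b), sig(a))
  expect_equal(ab$values, rev(ba$values), tolerance = 1e-10)
})

test_that("pearson mode equals per-lag correlation of overlapping segments", {
  set.seed(5)
  a <- rpois(200, 0.5); b <- rpois(200, 0.5)
  cf <- cross_correlation(sig(a), sig(b), mode = "pearson", max_lag_ms = 10)
  for (l in c(-7, -2, 0, 3, 9)) {
    if (l >= 0) r <- cor(a[1:(200 - l)], b[(1 + l):200])
    else r <- cor(a[(1 - l):200], b[1:(200 + l)])
    expect_equal(cf$values[cf$lags == l], r, tolerance = 1e-10)
  }
  expect_error(cross_correlation(sig(c(0, 1, 0, 0)), sig(c(0, 1, 0, 0)),
                                 mode = "pearson"),
               "at least 2 spikes")
})

test_that("gaussian smoothing is an identity for degenerate kernels", {
  set.seed(6)
  cf <- cross_correlation(sig(rpois(64, 0.5)), sig(rpois(64, 0.5)))
  expect_equal(smooth_correlation(cf, 0)$values, cf$values)
  # kernel narrower than one sample degenerates to the identity
  expect_equal(smooth_correlation(cf, 0.1)$values, cf$values)
})

test_that("gaussian smoothing preserves constants, mass and kernel shape", {
  lags <- seq(-50, 50, by = 1)
  const <- correlation_function(lags, rep(3, 101), "raw", c(0L, 1L), 1)
  expect_equal(smooth_correlation(const, 2)$values, rep(3, 101))

  delta <- correlation_function(lags, c(rep(0, 50), 10, rep(0, 50)),
                                "raw", c(0L, 1L), 1)
  sm <- smooth_correlation(delta, 3)
  expect_equal(sum(sm$values), 10, tolerance = 1e-6)
  expect_equal(sm$values[51], 10 * dnorm(0, sd = 3) /
                 sum(dnorm(-12:12, sd = 3)), tolerance = 1e-6)
  # shape: matches the analytic gaussian profile where mass is present
  expect_equal(sm$values[54] / sm$values[51], dnorm(3, sd = 3) / dnorm(0, sd = 3),
               tolerance = 1e-6)
})

test_that("peak detection finds constructed bumps with lag, width and flags", {
  lags <- seq(-10, 10, by = 0.1)
  bump <- function(mu, amp, sd) amp * exp(-((lags - mu) / sd)^2 / 2)
  one <- correlation_function(lags, bump(3, 5, 0.8), "raw", c(0L, 1L), 0.1)
  pk <- detect_peaks(one, T = 8)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$tau_ms, 3, tolerance = 0.11)
  # full width at half prominence of a gaussian: 2 * sqrt(2 log 2) * sd
  expect_equal(pk$width_ms, 2 * sqrt(2 * log(2)) * 0.8, tolerance = 0.05)

  two <- correlation_function(lags, bump(-4, 5, 0.6) + bump(6, 3, 0.6),
                              "raw", c(0L, 1L), 0.1)
  pk2 <- detect_peaks(two, T = 8)
  expect_equal(sort(pk2$tau_ms), c(-4, 6), tolerance = 0.11)

  # low-prominence ripples are rejected; zero-lag peaks are retained
  ripple <- correlation_function(lags, bump(0, 5, 0.8) + bump(5, 0.5, 0.4),
                                 "raw", c(0L, 1L), 0.1)
  pk3 <- detect_peaks(ripple, T = 8, min_prominence_frac = 0.2)
  expect_equal(pk3$tau_ms, 0)

  flat <- correlation_function(lags, rep(1, length(lags)), "raw", c(0L, 1L), 0.1)
  expect_equal(nrow(detect_peaks(flat, T = 8)), 0)
})

test_that("pairwise peaks on a zero-jitter chain sit at the composed delays", {
  chain <- generate_delta_motif("chain", delays = c(2, 3), event_rate = 5,
                                jitter_sd = 0, duration = 120, seed = 1)
  pg <- all_pairwise_peaks(chain$trains, dt = 0.1, T = 8, sigma = 0.05)
  expect_s3_class(pg, "peak_graph")
  expect_equal(pg$T_ms, 8)
  expect_equal(pg$sigma_ms, 0.05)
  top <- do.call(rbind, lapply(split(pg$peaks, paste(pg$peaks$j, pg$peaks$k)),
                               function(d) d[which.max(d$amplitude), ]))
  expect_equal(top$tau_ms[top$j == 0 & top$k == 1], 2, tolerance = 0.11)
  expect_equal(top$tau_ms[top$j == 1 & top$k == 2], 3, tolerance = 0.11)
  expect_equal(top$tau_ms[top$j == 0 & top$k == 2], 5, tolerance = 0.11)
  # storage convention: one record per unordered pair, j < k only
  expect_true(all(pg$peaks$j < pg$peaks$k))
})

test_that("the sparse pair correlogram equals the FFT cross-correlation", {
  set.seed(7)
  tr <- spike_train_set(list(sort(runif(80, 0, 5)), sort(runif(60, 0, 5))),
                        duration = 5)
  L <- 40L
  counts <- effconn:::pair_lag_counts(tr, dt = 1, L = L)[[1]]$counts
  sigs <- bin_spikes(tr, dt = 1)
  cf <- cross_correlation(sigs[[1]], sigs[[2]], max_lag_ms = L)
  expect_equal(as.numeric(counts), cf$values, tolerance = 1e-9)
})

test_that("indirect chain peaks are lower and wider than direct ones", {
  chain <- generate_delta_motif("chain", delays = c(2, 3), event_rate = 8,
                                jitter_sd = 0.4, duration = 240, seed = 2)
  pg <- all_pairwise_peaks(chain$trains, dt = 0.1, T = 8, sigma = 0.1)
  top <- do.call(rbind, lapply(split(pg$peaks, paste(pg$peaks$j, pg$peaks$k)),
                               function(d) d[which.max(d$amplitude), ]))
  a01 <- top[top$j == 0 & top$k == 1, ]
  a12 <- top[top$j == 1 & top$k == 2, ]
  a02 <- top[top$j == 0 & top$k == 2, ]
  expect_lt(a02$amplitude, a01$amplitude)
  expect_lt(a02$amplitude, a12$amplitude)
  expect_gt(a02$width_ms, a01$width_ms)
  expect_gt(a02$width_ms, a12$width_ms)
})

test_that("epsilon suggestion is the mean detected peak width", {
  pg <- peaks_from_table(3, j = c(0, 0), k = c(1, 2), tau = c(2, 3),
                         amp = c(5, 5), width = c(2, 4))
  expect_equal(suggest_epsilon(pg), 3)
  pg25 <- peaks_from_table(3, j = 0, k = 1, tau = 2, amp = 5, width = 2.5)
  expect_equal(suggest_epsilon(pg25), 2.5)
  empty <- peak_graph(3, pg$peaks[0, ], T_ms = 10, sigma_ms = 0.1)
  expect_error(suggest_epsilon(empty), "no surviving peaks")
})
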