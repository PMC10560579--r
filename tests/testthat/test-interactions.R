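mk_events <- function(onsets, ids = seq_along(onsets), labels = NULL) {
  ev <- data.frame(event_id = ids, onset_s = onsets, offset_s = onsets + 1)
  if (!is.null(labels)) ev$label <- labels
  ev
}

test_that("co-occurrence uses a strict 0.5 s window with greedy 1-to-1 matching", {
  a <- mk_events(c(10.0, 50.0))
  expect_equal(nrow(find_cooccurring(a, mk_events(10.4))), 1)   # 0.4 s: pair
  expect_equal(nrow(find_cooccurring(a, mk_events(10.5))), 0)   # 0.5 s: strict <
  # one A event equidistant from two B events: matched to the earlier only
  prs <- find_cooccurring(mk_events(10.0), mk_events(c(9.7, 10.3), ids = c(5L, 6L)))
  expect_equal(nrow(prs), 1)
  expect_equal(prs$event_id_b, 5L)
  # 1-to-1: two A near one B yields a single pair
  prs2 <- find_cooccurring(mk_events(c(10.0, 10.2)), mk_events(10.1))
  expect_equal(nrow(prs2), 1)
  # type combos and normalized incidence
  a2 <- mk_events(c(1, 5, 9), labels = c("SB", "NGB", "SB"))
  b2 <- mk_events(c(1.1, 5.1, 20), labels = c("SB", "NGB", "SB"))
  prs3 <- find_cooccurring(a2, b2)
  expect_setequal(prs3$type_combo, c("SB/SB", "NGB/NGB"))
  inc <- cooccurrence_incidence(prs3, a2, b2)
  expect_equal(unname(inc["SB/SB"]), 1 / 4)     # 1 pair / 4 SB events
  expect_equal(unname(inc["NGB/NGB"]), 1 / 2)
})

test_that("cross-spectral coherence is 1 for identical signals and peaks at shared components", {
  fs <- 500
  set.seed(30)
  x <- rnorm(4 * fs)
  cs <- cross_spectral_coherence(x, x, fs)
  expect_true(all(cs$coherence > 1 - 1e-9))
  expect_true(cs$rejected_artifact)            # mean > 0.8 by construction
  # shared 25 Hz component in independent noise: coherence peak at 25 Hz
  sh <- tone(25, 4, fs, amp = 2)
  a <- sh + rnorm(4 * fs); b <- sh + rnorm(4 * fs)
  cs2 <- cross_spectral_coherence(a, b, fs)
  pk <- cs2$freqs[which.max(cs2$coherence)]
  expect_equal(pk, 25, tolerance = 2.1)
  side <- cs2$coherence[cs2$freqs > 35 & cs2$freqs < 60]
  expect_gt(max(cs2$coherence), 3 * mean(side))
  expect_false(cs2$rejected_artifact)
  expect_error(cross_spectral_coherence(numeric(fs), x[1:fs], fs), "zero-variance")
  # coherence always within [0, 1]
  expect_true(all(cs2$coherence >= 0 & cs2$coherence <= 1))
})

test_that("imaginary coherence suppresses zero-lag coupling but finds phase-shifted coupling", {
  fs <- 500
  set.seed(31)
  n <- 8 * fs
  sh <- tone(20, 8, fs)
  sh90 <- cos(2 * pi * 20 * seq(1 / fs, 8, by = 1 / fs))
  # identical signals: coherence 1, imaginary coherence ~ 0
  x <- sh + rnorm(n, 0, 0.3)
  ic0 <- imaginary_coherence(x, x, fs)
  expect_lt(ic0$mean_coherence, 1e-9)
  # 90 degree shifted shared component: imaginary coherence peak at 20 Hz
  a <- sh + rnorm(n, 0, 0.5)
  b <- sh90 + rnorm(n, 0, 0.5)
  ic <- imaginary_coherence(a, b, fs)
  expect_equal(ic$freqs[which.max(ic$coherence)], 20, tolerance = 2.1)
  # independent noise: small everywhere
  ic2 <- imaginary_coherence(rnorm(n), rnorm(n), fs)
  expect_lt(ic2$mean_coherence, 0.4)
  # imaginary coherence is bounded by the coherence bin-wise
  cs <- cross_spectral_coherence(a, b, fs)
  expect_true(all(ic$coherence <= sqrt(cs$coherence) + 1e-9))
})

test_that("shuffle null separates shared from independent pairs and sits at the 95th percentile", {
  fs <- 500
  set.seed(32)
  mk_noise <- function() synthesize_burst("SB", 2, fs) +
    netbursts:::pink_noise(2 * fs, fs, 1, 30)
  segs_a <- lapply(1:12, function(i) mk_noise())
  segs_b <- lapply(1:12, function(i) mk_noise())
  nul <- coherence_null(segs_a, segs_b, fs, n_shuffle = 300, seed = 1)
  expect_equal(100 * mean(nul$null <= nul$threshold), 95, tolerance = 1)
  # strongly shared pairs: observed far above threshold
  shared <- lapply(1:12, function(i) mk_noise())
  segs_b2 <- lapply(1:12, function(i)
    0.9 * shared[[i]] + 0.45 * mk_noise())
  nul2 <- coherence_null(shared, segs_b2, fs, n_shuffle = 300, seed = 2)
  expect_true(nul2$significant)
  expect_gt(nul2$observed, nul2$threshold * 1.1)
  # degenerate single-shuffle null is warned
  expect_warning(coherence_null(segs_a[1:3], segs_b[1:3], fs, n_shuffle = 1),
                 "degenerate")
})

test_that("spike-field coherence detects trough-locked spiking and respects the spike minimum", {
  fs <- 1000
  lfp <- tone(10, 30, fs, amp = 50)
  troughs <- (which(diff(sign(diff(-lfp))) < 0) + 1) / fs
  sfc <- spike_field_coherence(troughs, lfp, fs, n_shuffle = 200, seed = 3)
  expect_true(sfc$significant)
  expect_true(any(sfc$significant_bins[sfc$freqs > 8 & sfc$freqs < 12]))
  # independent Poisson spikes: at most a few bins clear the 95th percentile
  set.seed(33)
  x <- netbursts:::pink_noise(30 * fs, fs, 1, 30)
  pois <- sort(runif(150, 0, 30))
  sfc2 <- spike_field_coherence(pois, x, fs, n_shuffle = 200, seed = 4)
  inband <- sfc2$freqs >= 4 & sfc2$freqs <= 40
  expect_lt(mean(sfc2$significant_bins[inband]), 0.25)
  # fewer than 10 spikes: flagged, no significance call
  sfc3 <- spike_field_coherence(pois[1:5], x, fs, n_shuffle = 50, seed = 5)
  expect_true(sfc3$insufficient_spikes)
  expect_true(is.na(sfc3$significant))
  expect_error(spike_field_coherence(pois + 100, x, fs), "overlap")
})

test_that("pre-whitened cross-correlation recovers constructed delays with documented signs", {
  fs <- 1000
  set.seed(34)
  n <- 6 * fs
  src <- netbursts:::pink_noise(n + fs, fs, 1, 30)
  d <- round(0.020 * fs)
  a <- src[1:n] + rnorm(n, 0, 3)              # cortex
  b <- src[(1 + d):(n + d)] + rnorm(n, 0, 3)  # striatum delayed copy... b(t) = a(t + 20ms)?
  # src[(1+d):(n+d)] at index t equals src at t + d, i.e. b runs AHEAD of a:
  # b leads -> positive lag under the convention (second region leads)
  lr <- prewhitened_xcorr_lag(a, b, fs, band = c(4, 16),
                              regions = c("cortex", "striatum"))
  expect_equal(lr$lag_ms, 20, tolerance = 2)
  expect_false(lr$putative_mono)
  expect_match(lr$sign_convention, "striatum leads cortex")
  # delayed partner: b(t) = a(t - 20 ms) -> cortex leads -> negative lag
  b2 <- c(rep(0, d), src[1:(n - d)]) + rnorm(n, 0, 3)
  lr2 <- prewhitened_xcorr_lag(a, b2, fs, band = c(4, 16),
                               regions = c("cortex", "striatum"))
  expect_equal(lr2$lag_ms, -20, tolerance = 2)
  # identical signals: zero lag, maximal correlation, putative monosynaptic
  lr3 <- prewhitened_xcorr_lag(a, a, fs, band = c(16, 40),
                               regions = c("cortex", "thalamus"))
  expect_equal(lr3$lag_ms, 0)
  expect_true(lr3$putative_mono)
  expect_gt(lr3$peak_corr, 0.99)
  # independent signals: peak correlation near the noise floor
  ind <- prewhitened_xcorr_lag(netbursts:::pink_noise(n, fs, 1, 30),
                               netbursts:::pink_noise(n, fs, 1, 30), fs,
                               band = c(4, 16), regions = c("a", "b"))
  expect_lt(ind$peak_corr, 4 / sqrt(n))   # ~ upper envelope of null ccf
  expect_error(prewhitened_xcorr_lag(a[1:500], b[1:500], fs), "1 s")
})

test_that("spike-train lags recover imposed shifts and support the population test", {
  set.seed(35)
  sa <- sort(runif(300, 0, 20))
  lr <- spiketrain_xcorr_lag(sa, sa + 0.003, 0, 20)
  expect_equal(lr$lag_ms, 3, tolerance = 1)
  expect_equal(spiketrain_xcorr_lag(sa, sa, 0, 20)$lag_ms, 0)
  expect_warning(out <- spiketrain_xcorr_lag(sa[1:3], sa, 0, 20), "insufficient")
  expect_null(out)
  # population: consistent -2 ms shift with jitter detected by the t-test
  lags <- vapply(1:60, function(i) {
    s <- sort(runif(120, 0, 20))
    spiketrain_xcorr_lag(s, s - 0.002 + rnorm(120, 0, 0.002), 0, 20)$lag_ms
  }, numeric(1))
  pop <- spiketrain_lag_test(lags)
  expect_equal(pop$mean_lag_ms, -2, tolerance = 0.8)
  expect_lt(pop$p_value, 0.01)
})

test_that("pair segment extraction intersects spans with a minimum-window fallback", {
  fs <- 100
  la <- seq_len(1000); lb <- seq_len(1000)
  ea <- data.frame(event_id = 1L, onset_s = 2, offset_s = 5)
  eb <- data.frame(event_id = 2L, onset_s = 3, offset_s = 6)
  pr <- data.frame(event_id_a = 1L, event_id_b = 2L)
  ps <- pair_segments(pr, ea, eb, la, lb, fs)
  expect_equal(ps$t0, 3); expect_equal(ps$t1, 5)
  expect_false(ps$short_span)
  # overlap under 0.5 s: single 0.5 s window from the later onset
  eb2 <- data.frame(event_id = 2L, onset_s = 4.8, offset_s = 6)
  ps2 <- pair_segments(pr, ea, eb2, la, lb, fs)
  expect_true(ps2$short_span)
  expect_equal(ps2$t1 - ps2$t0, 0.5)
  expect_equal(ps2$t0, 4.8)
})
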