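test_that("Gaussian fit to the RMS histogram matches a grid-search oracle", {
  set.seed(10)
  rms <- rnorm(3000, 20, 4)
  fit <- fit_rms_threshold(rms)
  expect_true(fit$converged)
  expect_false(fit$capped)
  # independent brute-force least-squares fit on the same histogram
  bw <- 2 * IQR(rms) / length(rms)^(1 / 3)
  nb <- max(50, ceiling(diff(range(rms)) / bw))
  h <- hist(rms, breaks = seq(min(rms), max(rms), length.out = nb + 1),
            plot = FALSE)
  g <- grid_gauss_fit(h$mids, h$counts, seq(18, 22, by = 0.01),
                      seq(3, 5, by = 0.01))
  expect_equal(fit$mu, unname(g["mu"]), tolerance = 0.05)
  expect_equal(fit$sigma, unname(g["sigma"]), tolerance = 0.05)
  expect_equal(fit$threshold, fit$mu + 3 * fit$sigma)
  expect_equal(fit$threshold, 32, tolerance = 1)
})

test_that("bimodal RMS distributions are fitted on the quiet mode, with the 50 uV cap", {
  set.seed(11)
  # quiet mode at 30, burst mode at 200: fitted mean near 30, not 64
  rms <- c(rnorm(4000, 30, 3), rnorm(1000, 200, 30))
  fit <- fit_rms_threshold(rms)
  expect_equal(fit$mu, 30, tolerance = 2)
  expect_false(fit$capped)
  # quiet mode at 80: mean capped at 50
  rms2 <- c(rnorm(4000, 80, 5), rnorm(1000, 300, 30))
  fit2 <- fit_rms_threshold(rms2)
  expect_true(fit2$capped)
  expect_equal(fit2$mu, 50, tolerance = 1e-6)
  expect_error(fit_rms_threshold(rnorm(10)), "50 RMS values")
})

test_that("supra-threshold runs become grid-aligned events without gap bridging", {
  fs <- 500
  # construct RMS pattern: two supra windows separated by one sub window
  quiet <- tone(10, 0.2, fs, amp = 1)
  loud <- tone(10, 0.2, fs, amp = 100)
  x <- c(rep(quiet, 3), loud, quiet, loud, rep(quiet, 3))
  ev <- detect_bursts(x, fs, fit = 50)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$onset_s, c(0.6, 1.0))
  expect_equal(ev$offset_s, c(0.8, 1.2))
  expect_true(all(abs(ev$onset_s / 0.2 - round(ev$onset_s / 0.2)) < 1e-9))
  # one inserted 1 s burst in noise: single event covering it
  set.seed(3)
  noise <- netbursts:::pink_noise(60 * fs, fs, 1, 20)
  burst <- synthesize_burst("SB", 1.0, fs, amplitude = 300, seed = 1)
  x2 <- noise
  x2[(20 * fs + 1):(20 * fs + length(burst))] <-
    x2[(20 * fs + 1):(20 * fs + length(burst))] + burst
  x2f <- bandpass(x2, fs, 4, 100)
  ev2 <- detect_bursts(x2f, fs, fit_rms_threshold(windowed_rms(x2f, fs)))
  big <- ev2[ev2$max_rms_uv > 100, ]
  expect_equal(nrow(big), 1)
  expect_lte(abs(big$onset_s - 20), 0.2)
  expect_lte(abs(big$offset_s - 21), 0.2)
})

test_that("noise-only supra-threshold window fraction matches the Gaussian tail when RMS is Gaussian", {
  # the printed threshold rule mu + 3 sigma implies P(window above threshold)
  # ~ 0.00135 for Gaussian-distributed RMS values
  set.seed(4)
  rms <- rnorm(200000, 20, 4)
  fit <- fit_rms_threshold(rms[1:5000])
  expect_equal(mean(rms > fit$threshold), pnorm(-3), tolerance = 0.002)
})

test_that("rejection filters label every printed criterion", {
  ev <- data.frame(event_id = 1:5, region = "r",
                   onset_s = c(0, 100, 200, 300, 400),
                   offset_s = c(25, 100.1, 201, 301, 401),
                   duration_s = c(25, 0.1, 1, 1, 1),
                   mean_rms_uv = c(50, 50, 50, 1200, 60),
                   max_rms_uv = 60, neg_peak_uv = -80,
                   n_peaks = c(9, 9, 4, 9, 9),
                   rejection_reason = "none")
  out <- apply_rejection_filters(ev)
  expect_equal(out$rejected$rejection_reason[out$rejected$event_id == 1], "too_long")
  expect_equal(out$rejected$rejection_reason[out$rejected$event_id == 2], "too_short")
  expect_equal(out$rejected$rejection_reason[out$rejected$event_id == 3], "too_few_peaks")
  expect_equal(out$rejected$rejection_reason[out$rejected$event_id == 4], "artifact")
  expect_equal(out$retained$event_id, 5)
  # boundary: exactly 5 peaks is retained, exactly 0.2 s and 20 s are retained
  ev2 <- ev[5, ]; ev2$n_peaks <- 5; ev2$duration_s <- 0.2
  expect_equal(nrow(apply_rejection_filters(ev2)$retained), 1)
  ev2$duration_s <- 20
  expect_equal(nrow(apply_rejection_filters(ev2)$retained), 1)
})

test_that("raising the threshold monotonically shrinks total burst time", {
  sim <- generate_recording(quick_config(seed = 8))
  x <- bandpass(get_channel(sim$recording, "cortex"), 1000, 4, 100)
  fit <- fit_rms_threshold(windowed_rms(x, 1000))
  tot <- vapply(c(2, 3, 4, 6), function(m) {
    ev <- detect_bursts(x, 1000, fit$mu + m * fit$sigma)
    sum(ev$duration_s)
  }, numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("envelope detector agrees with RMS detection on clear bursts", {
  sim <- generate_recording(quick_config(seed = 12))
  fs <- 1000
  x <- bandpass(get_channel(sim$recording, "cortex"), fs, 4, 100)
  ev_rms <- apply_rejection_filters(
    detect_bursts(x, fs, fit_rms_threshold(windowed_rms(x, fs))))$retained
  # bursts occupy ~20% of this fixture, so the per-recording percentile is
  # set at 85 to span them
  ev_env <- envelope_detect(x, fs, percentile = 85)
  ov <- overlap_fraction(ev_rms, ev_env)
  expect_gt(ov$mean, 60)
  # 100th percentile threshold -> nothing detected
  expect_equal(nrow(envelope_detect(x, fs, percentile = 100)), 0)
  # every truth event found by both detectors
  m1 <- match_events(ev_rms, sim$truth$events)
  m2 <- match_events(ev_env, sim$truth$events)
  expect_gt(m1$recall, 0.9)
  expect_gt(m2$recall, 0.9)
})

test_that("overlap fraction follows interval arithmetic", {
  A <- data.frame(onset_s = 0, offset_s = 2)
  B <- data.frame(onset_s = 1, offset_s = 3)
  ov <- overlap_fraction(A, B)
  expect_equal(ov$a_in_b, 50)
  expect_equal(ov$b_in_a, 50)
  expect_equal(overlap_fraction(A, A)$mean, 100)
  expect_equal(overlap_fraction(A, data.frame(onset_s = 5, offset_s = 6))$mean, 0)
})
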