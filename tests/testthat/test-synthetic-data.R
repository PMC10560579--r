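test_that("identical config and seed give bit-identical output", {
  a <- generate_recording(quick_config(duration_s = 30))
  b <- generate_recording(quick_config(duration_s = 30))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
})

test_that("configuration errors name the offending field", {
  expect_error(synth_config(cooccur_prob = 1.5), "cooccur_prob")
  expect_error(synth_config(sb_per_min = -1), "sb_per_min")
  expect_error(synth_config(fs = 50), "fs")
  expect_error(synth_config(sb_carrier_hz = 2), "sb_carrier_hz")
})

test_that("event counts follow the configured Poisson incidence", {
  # SB incidence 5/min over 10 minutes -> ~50 expected; average over seeded
  # runs should sit within Monte-Carlo error of the rate (placement thinning
  # removes a small fraction)
  counts <- vapply(1:20, function(s) {
    sim <- generate_recording(synth_config(
      duration_s = 600, fs = 250, regions = "cortex", sb_per_min = 5,
      ngb_per_min = 0, cooccur_prob = 0, spike_base_rate_hz = 0,
      ngb_nested_hz = 25, sb_carrier_hz = 8, seed = s))
    expect_true(all(sim$truth$events$kind == "SB"))
    nrow(sim$truth$events)
  }, numeric(1))
  expect_gt(mean(counts), 50 * 0.8)   # thinning loses < 20%
  expect_lt(mean(counts), 50 * 1.05)
})

test_that("zero incidence gives pure background noise and empty truth", {
  sim <- generate_recording(quick_config(sb_per_min = 0, ngb_per_min = 0,
                                         spike_base_rate_hz = 0))
  expect_equal(nrow(sim$truth$events), 0)
  expect_equal(nrow(sim$truth$spikes), 0)
  lfp <- get_channel(sim$recording, "cortex")
  expect_equal(sd(lfp), 30, tolerance = 0.05)   # configured noise RMS
})

test_that("all truth events lie within the recording and never overlap within a region", {
  sim <- generate_recording(quick_config(duration_s = 240, sb_per_min = 8,
                                         ngb_per_min = 4, seed = 3))
  ev <- sim$truth$events
  expect_true(all(ev$onset_s >= 0 & ev$offset_s <= 240))
  for (rg in unique(ev$region)) {
    er <- ev[ev$region == rg, ]
    er <- er[order(er$onset_s), ]
    if (nrow(er) > 1)
      expect_true(all(er$onset_s[-1] >= er$offset_s[-nrow(er)]))
  }
})

test_that("configured pair lag is recorded for every truth pair", {
  sim <- generate_recording(synth_config(
    duration_s = 200, fs = 500, regions = c("cortex", "striatum"),
    cooccur_prob = 1, lag_ms = 20, seed = 5))
  expect_gt(nrow(sim$truth$pairs), 3)
  expect_true(all(sim$truth$pairs$lag_ms == 20))
  # and the lag is physically imposed: onset difference matches
  for (i in seq_len(nrow(sim$truth$pairs))) {
    ea <- sim$truth$events[sim$truth$events$event_id == sim$truth$pairs$event_id_a[i], ]
    eb <- sim$truth$events[sim$truth$events$event_id == sim$truth$pairs$event_id_b[i], ]
    expect_equal(eb$onset_s - ea$onset_s, 0.020, tolerance = 1e-9)
  }
})

test_that("SB and NGB waveforms carry their designed spectral signatures", {
  fs <- 1000
  # SB with 10 Hz carrier: multitaper peak within 9-11 Hz
  w <- synthesize_burst("SB", 2, fs, carrier_hz = 10, seed = 2)
  expect_length(w, 2000)
  p <- multitaper_psd(w, fs)
  expect_gte(p$freqs[which.max(p$power)], 9)
  expect_lte(p$freqs[which.max(p$power)], 11)
  # SB: spindle-band power dominates the nested band
  expect_gt(band_fraction(p, c(4, 16)), band_fraction(p, c(16, 40)))
  # NGB with 30 Hz nested component: peaks in both bands
  wn <- synthesize_burst("NGB", 4, fs, carrier_hz = 8, nested_hz = 30, seed = 3)
  pn <- multitaper_psd(wn, fs)
  expect_gt(band_fraction(pn, c(4, 16)), 0.3)
  expect_gt(band_fraction(pn, c(25, 35)), 0.08)
  # zero amplitude -> all-zero waveform
  expect_true(all(synthesize_burst("SB", 1, fs, amplitude = 0, seed = 1) == 0))
  expect_error(synthesize_burst("SB", -1, fs), "positive")
})

test_that("averaged burst spectra place SB and NGB maxima in their bands", {
  fs <- 500
  sb_acc <- ngb_acc <- NULL
  base <- multitaper_psd(netbursts:::pink_noise(60 * fs, fs, 1, 30), fs)
  for (s in 1:5) {
    ps <- normalize_psd(multitaper_psd(synthesize_burst("SB", 2, fs, seed = s) +
                                         netbursts:::pink_noise(2 * fs, fs, 1, 30), fs), base)
    pn <- normalize_psd(multitaper_psd(synthesize_burst("NGB", 4, fs, seed = s) +
                                         netbursts:::pink_noise(4 * fs, fs, 1, 30), fs), base)
    sb_acc <- if (is.null(sb_acc)) ps$relative_power else sb_acc + ps$relative_power
    ngb_acc <- if (is.null(ngb_acc)) pn$relative_power else ngb_acc + pn$relative_power
  }
  f <- base$freqs
  sb_peak <- f[which.max(sb_acc)]
  expect_true(sb_peak >= 4 && sb_peak <= 16)
  # NGB: local maximum inside 16-40 Hz
  hi <- ngb_acc[f >= 16 & f <= 40]
  fhi <- f[f >= 16 & f <= 40]
  imax <- which.max(hi)
  expect_gt(fhi[imax], 16)
  expect_lt(fhi[imax], 40)
  expect_gt(hi[imax], mean(ngb_acc[f > 45 & f < 60]))
})

test_that("spike trains follow the configured rate and phase coupling", {
  fs <- 1000
  # coupling 0: homogeneous Poisson at base rate
  rates <- vapply(1:10, function(s)
    length(generate_spike_train(numeric(100 * fs), fs, 10, 0, seed = s)) / 100,
    numeric(1))
  expect_equal(mean(rates), 10, tolerance = 0.05)
  # base rate 0: empty train
  expect_length(generate_spike_train(numeric(fs), fs, 0, 0.5, seed = 1), 0)
  expect_error(generate_spike_train(numeric(fs), fs, 10, 1.2), "coupling")
  # strong coupling on a 10 Hz sinusoid concentrates spike phases
  lfp <- tone(10, 100, fs)
  st <- generate_spike_train(lfp, fs, 10, 0.9, seed = 4)
  phase <- Arg(netbursts:::analytic_signal(lfp))
  theta <- phase[pmax(1, round(st * fs))]
  expect_lt(rayleigh_p(theta), 0.01)
})
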