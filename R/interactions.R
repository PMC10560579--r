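#' Find co-occurring burst events across two regions
#'
#' Events from two regions are co-occurring when their onsets differ by
#' strictly less than `max_diff_s` (0.5 s). Matching is greedy one-to-one
#' by smallest onset difference, with the earlier event winning ties, so
#' no event participates in more than one pair.
#'
#' @param events_a,events_b retained event data frames from two distinct
#'   regions of the same recording (columns `event_id`, `onset_s`,
#'   optionally `label`).
#' @param max_diff_s co-occurrence window, seconds (default 0.5, strict).
#' @return data frame of pairs: `event_id_a`, `event_id_b`, `onset_diff_s`
#'   (b minus a), `type_combo` (`SB/SB`, `NGB/NGB`, `mixed`, or NA when
#'   labels are absent).
#' @export
find_cooccurring <- function(events_a, events_b, max_diff_s = 0.5) {
  out <- data.frame(event_id_a = integer(0), event_id_b = integer(0),
                    onset_diff_s = numeric(0), type_combo = character(0))
  if (nrow(events_a) == 0 || nrow(events_b) == 0) return(out)
  cand <- expand.grid(i = seq_len(nrow(events_a)), j = seq_len(nrow(events_b)))
  cand$diff <- events_b$onset_s[cand$j] - events_a$onset_s[cand$i]
  cand <- cand[abs(cand$diff) < max_diff_s, , drop = FALSE]
  cand <- cand[order(abs(cand$diff), events_a$onset_s[cand$i],
                     events_b$onset_s[cand$j]), , drop = FALSE]
  used_a <- logical(nrow(events_a)); used_b <- logical(nrow(events_b))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    combo <- if (!is.null(events_a$label) && !is.null(events_b$label)) {
      la <- events_a$label[i]; lb <- events_b$label[j]
      if (la == lb) paste(la, lb, sep = "/") else "mixed"
    } else NA_character_
    out <- rbind(out, data.frame(event_id_a = events_a$event_id[i],
                                 event_id_b = events_b$event_id[j],
                                 onset_diff_s = cand$diff[r],
                                 type_combo = combo))
  }
  out[order(out$onset_diff_s), , drop = FALSE]
}

#' Normalized co-occurrence incidence per burst-type combination
#'
#' Pair counts divided by the total number of events in the paired
#' classes across both regions, controlling for each class's absolute
#' incidence.
#'
#' @param pairs data frame from [find_cooccurring()] with `type_combo`.
#' @param events_a,events_b labeled event data frames.
#' @return named numeric vector of normalized incidences per combination.
#' @export
cooccurrence_incidence <- function(pairs, events_a, events_b) {
  combos <- c("SB/SB", "NGB/NGB", "mixed")
  n_of <- function(events, lab) sum(events$label == lab)
  denom <- c("SB/SB" = n_of(events_a, "SB") + n_of(events_b, "SB"),
             "NGB/NGB" = n_of(events_a, "NGB") + n_of(events_b, "NGB"),
             "mixed" = n_of(events_a, "SB") + n_of(events_b, "SB") +
               n_of(events_a, "NGB") + n_of(events_b, "NGB"))
  counts <- vapply(combos, function(cb) sum(pairs$type_combo == cb, na.rm = TRUE),
                   numeric(1))
  ifelse(denom > 0, counts / denom, NA_real_)
}

# Welch cross-spectral estimate: 0.5 s Hann segments, zero overlap, linear
# detrend per segment. Returns averaged auto- and cross-spectra.
welch_cross <- function(x, y, fs, window_s = 0.5) {
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_arg("undefined coherence: zero-variance segment")
  w <- round(window_s * fs)
  single <- n < w
  if (single) w <- n
  nseg <- n %/% w
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, w - 1) / (w - 1))
  nfft <- next_pow2(w)
  nfreq <- nfft %/% 2 + 1
  Sxx <- Syy <- numeric(nfreq); Sxy <- complex(nfreq)
  tt <- seq_len(w) - (w + 1) / 2        # centered time basis
  stt <- sum(tt^2)
  detrend <- function(v) v - mean(v) - tt * sum(tt * v) / stt
  for (s in seq_len(nseg)) {
    idx <- ((s - 1) * w + 1):(s * w)
    xs <- detrend(x[idx]) * win
    ys <- detrend(y[idx]) * win
    X <- stats::fft(c(xs, numeric(nfft - w)))[seq_len(nfreq)]
    Y <- stats::fft(c(ys, numeric(nfft - w)))[seq_len(nfreq)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  list(freqs = (0:(nfreq - 1)) * fs / nfft,
       Sxx = Sxx / nseg, Syy = Syy / nseg, Sxy = Sxy / nseg,
       n_segments = nseg, single_window = single)
}

coh_result <- function(freqs, coh, band, n_segments, single_window,
                       kind, null_threshold = NA_real_) {
  inband <- freqs >= band[1] & freqs <= band[2]
  mean_coh <- mean(coh[inband])
  structure(list(freqs = freqs, coherence = coh, mean_coherence = mean_coh,
                 band = band, null_threshold = null_threshold,
                 significant = if (is.na(null_threshold)) NA else mean_coh > null_threshold,
                 rejected_artifact = mean_coh > 0.8,
                 n_segments = n_segments, single_window = single_window,
                 kind = kind),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result:%s> mean %.3f over %g-%g Hz (%d segment(s))%s\n",
              x$kind, x$mean_coherence, x$band[1], x$band[2], x$n_segments,
              if (isTRUE(x$rejected_artifact)) " [artifact: > 0.8]" else ""))
  invisible(x)
}

#' Cross-spectral coherence between two burst segments
#'
#' Magnitude-squared coherence by Welch's method (0.5 s Hann windows, zero
#' overlap, per-segment linear detrend) over the pair's common time span.
#' The summary statistic is the mean coherence over 4-40 Hz, the union of
#' the two analysis bands. Pairs with mean coherence above 0.8 are flagged
#' as artifacts (movement produces implausibly synchronous signals). With
#' a single analysis window the estimate is degenerate (identically 1) and
#' flagged via `single_window`.
#'
#' @param seg_a,seg_b time-aligned LFP segments, microvolts.
#' @param fs sampling rate.
#' @param band averaging band for the summary, Hz (default `c(4, 40)`).
#' @param window_s Welch window, seconds (default 0.5).
#' @param null_threshold optional shuffle-null threshold from
#'   [coherence_null()]; when supplied, `significant` is filled in.
#' @return `coherence_result` object.
#' @export
cross_spectral_coherence <- function(seg_a, seg_b, fs, band = c(4, 40),
                                     window_s = 0.5, null_threshold = NA_real_) {
  wc <- welch_cross(seg_a, seg_b, fs, window_s)
  coh <- Mod(wc$Sxy)^2 / (wc$Sxx * wc$Syy)
  coh[!is.finite(coh)] <- 0
  coh_result(wc$freqs, pmin(coh, 1), band, wc$n_segments, wc$single_window,
             "csc", null_threshold)
}

#' Imaginary coherence between two burst segments
#'
#' Absolute imaginary part of the normalized cross-spectrum (coherency),
#' same Welch windowing as [cross_spectral_coherence()]. Insensitive to
#' zero-lag coupling, hence to volume conduction.
#'
#' @inheritParams cross_spectral_coherence
#' @return `coherence_result` object.
#' @export
imaginary_coherence <- function(seg_a, seg_b, fs, band = c(4, 40),
                                window_s = 0.5, null_threshold = NA_real_) {
  wc <- welch_cross(seg_a, seg_b, fs, window_s)
  coherency <- wc$Sxy / sqrt(wc$Sxx * wc$Syy)
  coh <- abs(Im(coherency))
  coh[!is.finite(coh)] <- 0
  coh_result(wc$freqs, pmin(coh, 1), band, wc$n_segments, wc$single_window,
             "imaginary", null_threshold)
}

#' Shuffle-null significance threshold for pair coherence
#'
#' Builds the null distribution of mean coherence by re-pairing the burst
#' events at random (a derangement, so no event keeps its true partner)
#' `n_shuffle` times, computing the mean across shuffled pairs of the
#' per-pair mean coherence at each iteration. The significance threshold
#' is the 95th percentile of the null means. With fewer pairs than needed
#' for a derangement, partners are resampled with replacement (warned).
#'
#' @param segs_a,segs_b lists of time-aligned burst segments (the true
#'   pairing is `segs_a[[i]]` with `segs_b[[i]]`).
#' @param fs sampling rate.
#' @param n_shuffle number of shuffles (default 1000).
#' @param method `"csc"` or `"imaginary"`.
#' @param band summary band, Hz.
#' @param seed integer seed for the shuffles.
#' @return list with `threshold` (95th percentile), `null` (vector of
#'   shuffle means), `observed` (true-pairing mean), `significant`,
#'   `percentile` (the quantile level used, 95).
#' @export
coherence_null <- function(segs_a, segs_b, fs, n_shuffle = 1000,
                           method = c("csc", "imaginary"), band = c(4, 40),
                           seed = 1) {
  method <- match.arg(method)
  np <- length(segs_a)
  if (np < 2 || np != length(segs_b))
    stop_arg("need at least 2 pairs with matching lists")
  if (n_shuffle < 2)
    warning("degenerate null: threshold from a single shuffled mean")
  M <- coherence_matrix(segs_a, segs_b, fs, method = method, band = band)
  observed <- mean(diag(M))
  set.seed(as.integer(seed))
  derange <- function(n) {
    for (try in 1:100) {
      p <- sample.int(n)
      if (!any(p == seq_len(n))) return(p)
    }
    warning("could not derange pair indices; sampling partners with replacement")
    sample.int(n, replace = TRUE)
  }
  null <- vapply(seq_len(max(1, n_shuffle)), function(s) {
    p <- derange(np)
    mean(M[cbind(seq_len(np), p)])
  }, numeric(1))
  thr <- stats::quantile(null, 0.95, names = FALSE)
  list(threshold = thr, null = null, observed = observed,
       significant = observed > thr, percentile = 95)
}

#' Spike-field coherence with a spike-shuffle null
#'
#' Spike times are binned in 2 ms segments to a continuous signal; the LFP
#' is band-passed 4-80 Hz and resampled to the same 500 S/s rate. The
#' coherence is the absolute real component of the normalized
#' cross-spectrum, estimated with the same Welch windowing as the other
#' coherence measures. Significance per frequency bin comes from the 95th
#' percentile across `n_shuffle` random relocations of the spike times
#' within the segment span. Segments with fewer than 10 spikes get no
#' significance call (`insufficient_spikes`).
#'
#' @param spike_times spike times within the segment, seconds (absolute).
#' @param lfp LFP signal for the same span, microvolts.
#' @param fs LFP sampling rate.
#' @param t0 time of the first LFP sample, seconds.
#' @param bin_ms spike bin, milliseconds (default 2).
#' @param n_shuffle shuffles for the null (default 1000).
#' @param band summary band, Hz (default 4-40).
#' @param seed integer seed.
#' @return `coherence_result` with extra fields `null_per_bin`,
#'   `significant_bins`, `insufficient_spikes`, `n_spikes`.
#' @export
spike_field_coherence <- function(spike_times, lfp, fs, t0 = 0, bin_ms = 2,
                                  n_shuffle = 1000, band = c(4, 40), seed = 1) {
  dur <- length(lfp) / fs
  if (dur <= 0) stop_arg("empty LFP segment")
  spike_times <- spike_times - t0
  spike_times <- spike_times[spike_times >= 0 & spike_times < dur]
  if (length(spike_times) == 0)
    stop_arg("no overlap between the spike train and the LFP span")
  fs_b <- 1000 / bin_ms
  lf <- bandpass(lfp, fs, 4, min(80, fs / 2 - 1))
  t_new <- seq(0, dur - 1 / fs_b, by = 1 / fs_b)
  lfp_ds <- stats::approx(seq(0, dur - 1 / fs, by = 1 / fs), lf, xout = t_new,
                          rule = 2)$y
  bin_train <- function(tt) {
    tabulate(pmin(length(t_new), floor(tt * fs_b) + 1L), nbins = length(t_new))
  }
  sfc_of <- function(tt) {
    wc <- welch_cross(bin_train(tt), lfp_ds, fs_b)
    v <- abs(Re(wc$Sxy / sqrt(wc$Sxx * wc$Syy)))
    v[!is.finite(v)] <- 0
    list(freqs = wc$freqs, coh = pmin(v, 1), wc = wc)
  }
  obs <- sfc_of(spike_times)
  res <- coh_result(obs$freqs, obs$coh, band, obs$wc$n_segments,
                    obs$wc$single_window, "spike_field")
  res$n_spikes <- length(spike_times)
  res$insufficient_spikes <- length(spike_times) < 10
  if (res$insufficient_spikes) {
    res$null_per_bin <- NULL
    res$significant_bins <- NULL
    res$significant <- NA
    return(res)
  }
  set.seed(as.integer(seed))
  null <- matrix(NA_real_, n_shuffle, length(obs$freqs))
  for (s in seq_len(n_shuffle)) {
    null[s, ] <- sfc_of(stats::runif(length(spike_times), 0, dur))$coh
  }
  res$null_per_bin <- apply(null, 2, stats::quantile, probs = 0.95, names = FALSE)
  res$significant_bins <- obs$coh > res$null_per_bin
  res$significant <- any(res$significant_bins[obs$freqs >= band[1] &
                                                obs$freqs <= band[2]])
  res
}

# Per-segment Welch window spectra (Hann, linear detrend), cached so the
# all-pairs coherence matrix reuses each segment's FFTs. All segments are
# reduced to the window count of the shortest so cross-pairings are
# comparable.
welch_window_spectra <- function(segs, fs, window_s = 0.5) {
  w <- round(window_s * fs)
  nfft <- next_pow2(w)
  nfreq <- nfft %/% 2 + 1
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, w - 1) / (w - 1))
  tt <- seq_len(w) - (w + 1) / 2
  stt <- sum(tt^2)
  lapply(segs, function(x) {
    nseg <- length(x) %/% w
    if (nseg == 0) stop_arg("segment shorter than one %g s window", window_s)
    X <- matrix(0i, nfreq, nseg)
    for (s in seq_len(nseg)) {
      xs <- x[((s - 1) * w + 1):(s * w)]
      xs <- (xs - mean(xs) - tt * sum(tt * xs) / stt) * win
      X[, s] <- stats::fft(c(xs, numeric(nfft - w)))[seq_len(nfreq)]
    }
    X
  })
}

# all-pairs mean coherence over `band`: entry [i, j] equals the summary
# statistic of cross_spectral_coherence / imaginary_coherence for
# (segs_a[[i]], segs_b[[j]]) truncated to the common window count
coherence_matrix <- function(segs_a, segs_b, fs, method = "csc",
                             band = c(4, 40), window_s = 0.5) {
  Xa <- welch_window_spectra(segs_a, fs, window_s)
  Xb <- welch_window_spectra(segs_b, fs, window_s)
  w <- round(window_s * fs)
  nfft <- next_pow2(w)
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  inband <- freqs >= band[1] & freqs <= band[2]
  M <- matrix(NA_real_, length(Xa), length(Xb))
  for (i in seq_along(Xa)) for (j in seq_along(Xb)) {
    ns <- min(ncol(Xa[[i]]), ncol(Xb[[j]]))
    A <- Xa[[i]][, seq_len(ns), drop = FALSE]
    B <- Xb[[j]][, seq_len(ns), drop = FALSE]
    Sxx <- rowMeans(Mod(A)^2); Syy <- rowMeans(Mod(B)^2)
    Sxy <- rowMeans(A * Conj(B))
    v <- if (method == "csc") Mod(Sxy)^2 / (Sxx * Syy)
         else abs(Im(Sxy / sqrt(Sxx * Syy)))
    v[!is.finite(v)] <- 0
    M[i, j] <- mean(pmin(v, 1)[inband])
  }
  M
}

# AR pre-whitening: fit AR(p) with p chosen by AIC over 1..order_max and
# return residuals aligned to the input (leading NAs dropped consistently)
ar_residuals <- function(x, order_max = 10) {
  fit <- tryCatch(stats::ar(x, aic = TRUE, order.max = order_max,
                            method = "burg"),
                  error = function(e) NULL)
  if (is.null(fit) || fit$order == 0 || all(is.na(fit$resid))) {
    return(list(resid = diff(x), order = NA_integer_, fallback = TRUE))
  }
  r <- fit$resid
  list(resid = r[!is.na(r)], order = fit$order, fallback = FALSE,
       lead = sum(is.na(r)))
}

#' Propagation lag from pre-whitened LFP cross-correlation
#'
#' Both signals are band-pass filtered to the analysis band (4-16 Hz for
#' spindle bursts, 16-40 Hz for nested gamma), pre-whitened by fitting an
#' AR model to each independently (order by AIC over 1-10; `reference`
#' mode instead filters both signals through the model fitted to the first
#' signal) and the normalized cross-correlation of the residuals computed.
#' Pre-whitening removes each signal's autocorrelation, which would
#' otherwise produce broad spurious cross-correlation peaks at the
#' oscillation period. The lag is the argmax within +/-50 ms.
#'
#' Sign convention: a positive lag means the second signal (`region_b`)
#' leads the first; matching the conventions used for developmental
#' cortex/striatum/thalamus pairs when called in the canonical orders
#' (cortex, striatum), (thalamus, striatum), (cortex, thalamus) — e.g. for
#' a cortex-striatum pair a positive lag indicates striatum leading and a
#' negative lag cortex leading. Lags of magnitude below 20 ms are
#' considered putative monosynaptic interactions.
#'
#' @param lfp_a,lfp_b time-aligned LFP segments from the two regions.
#' @param fs sampling rate.
#' @param band analysis band, Hz: `c(4, 16)` or `c(16, 40)`.
#' @param regions character pair naming (region_a, region_b), for the
#'   convention string.
#' @param max_lag_ms lag search bound, milliseconds (default 50).
#' @param mode `"independent"` (default: each signal whitened by its own
#'   AR fit) or `"reference"` (both filtered by the model of `lfp_a`).
#' @return object of class `lag_result`: `lag_ms` (signed), `peak_corr`,
#'   `band`, `region_pair`, `putative_mono` (|lag| < 20 ms),
#'   `sign_convention`, `ar_orders`, `prewhiten_fallback`.
#' @export
prewhitened_xcorr_lag <- function(lfp_a, lfp_b, fs, band = c(4, 16),
                                  regions = c("a", "b"), max_lag_ms = 50,
                                  mode = c("independent", "reference")) {
  mode <- match.arg(mode)
  n <- min(length(lfp_a), length(lfp_b))
  if (n / fs < 1) stop_arg("common span must be at least 1 s")
  a <- bandpass(lfp_a[seq_len(n)], fs, band[1], band[2])
  b <- bandpass(lfp_b[seq_len(n)], fs, band[1], band[2])
  if (mode == "independent") {
    ra <- ar_residuals(a); rb <- ar_residuals(b)
    orders <- c(ra$order, rb$order)
    fallback <- ra$fallback || rb$fallback
    m <- min(length(ra$resid), length(rb$resid))
    # align from the end: residual t corresponds to sample t
    av <- utils::tail(ra$resid, m); bv <- utils::tail(rb$resid, m)
  } else {
    fit <- tryCatch(stats::ar(a, aic = TRUE, order.max = 10, method = "burg"),
                    error = function(e) NULL)
    if (is.null(fit) || fit$order == 0) {
      av <- diff(a); bv <- diff(b); orders <- NA_integer_; fallback <- TRUE
    } else {
      flt <- function(x) stats::filter(x, c(1, -fit$ar), method = "convolution",
                                       sides = 1)
      av <- as.numeric(stats::na.omit(flt(a)))
      bv <- as.numeric(stats::na.omit(flt(b)))
      orders <- c(fit$order, fit$order); fallback <- FALSE
    }
  }
  if (fallback)
    warning("AR pre-whitening unavailable; fell back to first differencing")
  L <- round(max_lag_ms / 1000 * fs)
  cc <- stats::ccf(bv, av, lag.max = L, plot = FALSE, demean = TRUE)
  tau <- cc$lag[, 1, 1]
  r <- cc$acf[, 1, 1]
  k <- which.max(r)
  lag_ms <- -tau[k] * 1000 / fs   # positive: region_b leads
  structure(list(lag_ms = lag_ms, peak_corr = r[k], band = band,
                 region_pair = regions,
                 putative_mono = abs(lag_ms) < 20,
                 sign_convention = sprintf(
                   "positive lag: %s leads %s; negative lag: %s leads %s",
                   regions[2], regions[1], regions[1], regions[2]),
                 ar_orders = orders, prewhiten_fallback = fallback),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("<lag_result> %s-%s %g-%g Hz: lag %.1f ms (r = %.3f)%s\n",
              x$region_pair[1], x$region_pair[2], x$band[1], x$band[2],
              x$lag_ms, x$peak_corr,
              if (isTRUE(x$putative_mono)) " [putative monosynaptic]" else ""))
  invisible(x)
}

#' Spike-train cross-correlation lag
#'
#' Both spike trains are smoothed with a 2 ms SD Gaussian kernel
#' ([smooth_spike_train()]) and the normalized cross-correlation of the
#' two continuous signals computed; the lag is the argmax within
#' +/-10 ms. Sign convention: a positive lag means train B trails
#' (follows) train A — shifting B later by 3 ms yields +3 ms.
#'
#' @param times_a,times_b spike times of the two trains, seconds.
#' @param t_start,t_end common analysis span, seconds.
#' @param bin_ms smoothing bin, milliseconds (default 1, giving 1 ms lag
#'   resolution).
#' @param kernel_sd_ms Gaussian kernel SD (default 2).
#' @param max_lag_ms lag bound (default 10).
#' @param min_spikes minimum spikes per train (default 5); fewer returns
#'   `NULL` with a warning so population analyses can skip the pair.
#' @return `lag_result` object (band `NA`), or `NULL` if spikes are
#'   insufficient.
#' @export
spiketrain_xcorr_lag <- function(times_a, times_b, t_start, t_end, bin_ms = 1,
                                 kernel_sd_ms = 2, max_lag_ms = 10,
                                 min_spikes = 5) {
  ina <- times_a[times_a >= t_start & times_a < t_end]
  inb <- times_b[times_b >= t_start & times_b < t_end]
  if (length(ina) < min_spikes || length(inb) < min_spikes) {
    warning(sprintf("insufficient spikes (%d, %d); pair skipped",
                    length(ina), length(inb)))
    return(NULL)
  }
  sa <- smooth_spike_train(ina, t_start, t_end, bin_ms, kernel_sd_ms)
  sb <- smooth_spike_train(inb, t_start, t_end, bin_ms, kernel_sd_ms)
  L <- round(max_lag_ms / bin_ms)
  cc <- stats::ccf(sb$intensity, sa$intensity, lag.max = L, plot = FALSE,
                   demean = TRUE)
  tau <- cc$lag[, 1, 1]; r <- cc$acf[, 1, 1]
  k <- which.max(r)
  lag_ms <- tau[k] * bin_ms    # positive: train B trails train A
  structure(list(lag_ms = lag_ms, peak_corr = r[k], band = NA,
                 region_pair = c("a", "b"),
                 putative_mono = abs(lag_ms) < 20,
                 sign_convention = "positive lag: train B follows train A",
                 n_spikes = c(length(ina), length(inb))),
            class = "lag_result")
}

#' Population test on per-pair spike-train lags
#'
#' Collects the peak lags of many co-occurring burst pairs and tests their
#' mean against zero with a one-sample t-test: a consistent sign indicates
#' a consistent leader across the population.
#'
#' @param lags_ms numeric vector of per-pair peak lags, milliseconds.
#' @return list with `mean_lag_ms`, `t`, `df`, `p_value`, `n`.
#' @export
spiketrain_lag_test <- function(lags_ms) {
  lags_ms <- lags_ms[!is.na(lags_ms)]
  if (length(lags_ms) < 2) stop_arg("need at least 2 lags")
  tt <- one_sample_t(lags_ms, mu0 = 0)
  list(mean_lag_ms = mean(lags_ms), t = tt$t, df = tt$df, p_value = tt$p,
       n = length(lags_ms))
}

#' Extract the time-aligned analysis segments of a co-occurring pair
#'
#' The analysis span is the intersection of the two event spans; when that
#' is shorter than one Welch window (0.5 s) a single 0.5 s window starting
#' at the later onset is used instead (flagged).
#'
#' @param pair one row of the [find_cooccurring()] output.
#' @param events_a,events_b the event tables the pair refers to.
#' @param lfp_a,lfp_b full-recording LFP signals of the two regions.
#' @param fs sampling rate.
#' @param min_span_s minimum span, seconds (default 0.5).
#' @return list with `seg_a`, `seg_b`, `t0`, `t1`, `short_span` flag.
#' @export
pair_segments <- function(pair, events_a, events_b, lfp_a, lfp_b, fs,
                          min_span_s = 0.5) {
  ea <- events_a[events_a$event_id == pair$event_id_a, ]
  eb <- events_b[events_b$event_id == pair$event_id_b, ]
  t0 <- max(ea$onset_s, eb$onset_s)
  t1 <- min(ea$offset_s, eb$offset_s)
  short <- (t1 - t0) < min_span_s
  if (short) t1 <- t0 + min_span_s
  list(seg_a = slice_signal(lfp_a, fs, t0, t1),
       seg_b = slice_signal(lfp_b, fs, t0, t1),
       t0 = t0, t1 = t1, short_span = short)
}
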