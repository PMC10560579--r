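#' Zero-phase Butterworth band-pass filter
#'
#' Applies a third-order (by default) Butterworth band-pass filter in both
#' directions (`signal::filtfilt`), giving zero phase distortion. Zero-phase
#' filtering is deliberate: downstream lag estimation would otherwise be
#' biased by the filter's group delay. Note that forward-backward application
#' doubles the effective filter order.
#'
#' The two standard analysis bands are 1-100 Hz for LFP work (4-100 Hz for
#' burst detection) and 400-4000 Hz for multi-unit activity.
#'
#' @param x numeric vector, raw signal in microvolts.
#' @param fs sampling rate, samples/second.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order filter order (default 3).
#' @return filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, low_hz, high_hz, order = 3) {
  if (!is.numeric(x)) stop_arg("signal must be numeric")
  if (low_hz <= 0 || high_hz <= low_hz)
    stop_arg("band edges must satisfy 0 < low_hz < high_hz")
  if (high_hz >= fs / 2)
    stop_arg("high band edge %g Hz is at or above Nyquist (%g Hz)", high_hz, fs / 2)
  if (order < 1) stop_arg("filter order must be >= 1")
  if (length(x) <= 3 * order)
    stop_arg("signal too short (%d samples) for order-%d filtering", length(x), order)
  if (all(x == 0)) return(x)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Windowed root-mean-square amplitude
#'
#' RMS over consecutive non-overlapping windows aligned to the signal start;
#' a trailing partial window is dropped. The 200 ms default window is the
#' grid on which burst events are defined.
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate, samples/second.
#' @param window_s window length in seconds (default 0.2).
#' @return numeric vector, one RMS value (microvolts) per window.
#' @export
windowed_rms <- function(x, fs, window_s = 0.2) {
  w <- round(window_s * fs)
  if (w < 1 || length(x) < w)
    stop_arg("signal shorter than one %g s window", window_s)
  nwin <- floor(length(x) / w)
  m <- matrix(x[seq_len(nwin * w)]^2, nrow = w)
  sqrt(colMeans(m))
}

#' Detect multi-unit spikes by negative thresholding
#'
#' Threshold is set `sd_mult` (default 5) standard deviations below the MUA
#' baseline. Baseline SD defaults to the robust estimate
#' `median(|x|) / 0.6745`, which is insensitive to the spikes themselves;
#' set `robust = FALSE` for the plain sample SD. For each maximal run of
#' consecutive sub-threshold samples one spike is placed at the run's local
#' minimum and a 1 ms waveform snippet centered there is extracted
#' (zero-padded at the recording edges). Candidates whose waveform maximum
#' does not exceed 0 microvolts are rejected.
#'
#' @param x MUA signal, already band-passed 400-4000 Hz, in microvolts.
#' @param fs sampling rate, samples/second.
#' @param sd_mult threshold multiplier (default 5).
#' @param robust use the median-based baseline SD estimate (default TRUE).
#' @return object of class `spike_train`: list with `times` (seconds),
#'   `amplitudes` (trough depth, microvolts), `waveforms` (spikes x samples
#'   matrix), `threshold_uv`, `fs`.
#' @export
detect_spikes <- function(x, fs, sd_mult = 5, robust = TRUE) {
  sigma <- if (robust) stats::median(abs(x)) / 0.6745 else stats::sd(x)
  if (!is.finite(sigma) || sigma == 0) {
    warning("flat MUA signal: baseline SD is zero, returning empty spike train")
    return(spike_train(numeric(0), numeric(0),
                       matrix(numeric(0), 0, round(0.001 * fs)), 0, fs))
  }
  thr <- -sd_mult * sigma
  runs <- true_runs(x < thr)
  wlen <- max(3L, round(0.001 * fs))
  half <- wlen %/% 2L
  times <- numeric(0); amps <- numeric(0)
  wfs <- matrix(numeric(0), 0, wlen)
  for (i in seq_len(nrow(runs))) {
    seg <- runs[i, 1]:runs[i, 2]
    ctr <- seg[which.min(x[seg])]
    idx <- (ctr - half):(ctr - half + wlen - 1L)
    wf <- numeric(wlen)
    ok <- idx >= 1L & idx <= length(x)
    wf[ok] <- x[idx[ok]]
    if (max(wf) <= 0) next   # biphasic requirement: must rebound above 0 uV
    times <- c(times, (ctr - 1) / fs)
    amps <- c(amps, x[ctr])
    wfs <- rbind(wfs, wf)
  }
  spike_train(times, amps, wfs, thr, fs)
}

spike_train <- function(times, amplitudes, waveforms, threshold_uv, fs) {
  structure(list(times = times, amplitudes = amplitudes,
                 waveforms = waveforms, threshold_uv = threshold_uv, fs = fs),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes, threshold %.2f uV\n",
              length(x$times), x$threshold_uv))
  invisible(x)
}

#' Gaussian-smoothed spike train
#'
#' Bins spike times and convolves the counts with a unit-area Gaussian
#' kernel (SD 2 ms by default, truncated at 4 SD), producing the continuous
#' intensity signal used for spike-train cross-correlation. The series sums
#' to the spike count up to edge truncation.
#'
#' @param times spike times in seconds.
#' @param t_start,t_end span of the output series, seconds.
#' @param bin_ms bin width, milliseconds (default 2).
#' @param kernel_sd_ms Gaussian kernel SD, milliseconds (default 2).
#' @return list with `t` (bin centers, s), `intensity` (spikes per bin,
#'   smoothed), `bin_s`.
#' @export
smooth_spike_train <- function(times, t_start, t_end, bin_ms = 2, kernel_sd_ms = 2) {
  if (t_end <= t_start) stop_arg("t_end must exceed t_start")
  bin_s <- bin_ms / 1000
  edges <- seq(t_start, t_end, by = bin_s)
  if (length(edges) < 2) stop_arg("span shorter than one bin")
  times <- times[times >= t_start & times < edges[length(edges)]]
  counts <- if (length(times)) {
    tabulate(findInterval(times, edges), nbins = length(edges) - 1)
  } else numeric(length(edges) - 1)
  sd_bins <- kernel_sd_ms / bin_ms
  half <- ceiling(4 * sd_bins)
  k <- stats::dnorm(-half:half, sd = sd_bins)
  k <- k / sum(k)
  sm <- stats::convolve(counts, rev(k), type = "open")
  sm <- sm[(half + 1):(half + length(counts))]
  list(t = edges[-length(edges)] + bin_s / 2, intensity = sm, bin_s = bin_s)
}

#' Spike rate over an interval
#'
#' Number of spikes in the half-open interval `[onset, offset)` divided by
#' its duration.
#'
#' @param times spike times, seconds.
#' @param onset,offset interval bounds, seconds.
#' @return rate in Hz.
#' @export
spike_rate <- function(times, onset, offset) {
  if (offset <= onset) stop_arg("zero-length interval")
  sum(times >= onset & times < offset) / (offset - onset)
}

#' Windowed spike rate for inactivation experiments
#'
#' Rate comparison used for pharmacological inactivation recordings: rates
#' are averaged across the three channels centred on the target channel,
#' control recordings are analyzed from 5 min onwards (and must last at
#' least 5 min), and inactivation ("lidocaine") recordings are restricted
#' to the 5-25 min window where the block is maximal.
#'
#' @param trains list of spike-time vectors (seconds), one per channel
#'   (normally three).
#' @param duration_s total recording duration, seconds.
#' @param condition `"control"` or `"lidocaine"`.
#' @return mean rate across channels, Hz.
#' @export
windowed_spike_rate <- function(trains, duration_s, condition = c("control", "lidocaine")) {
  condition <- match.arg(condition)
  if (duration_s < 300)
    stop_arg("recording shorter than 5 min cannot be used (duration %.1f s)", duration_s)
  onset <- 300
  offset <- if (condition == "lidocaine") min(duration_s, 1500) else duration_s
  if (offset <= onset) stop_arg("no analyzable window in recording")
  mean(vapply(trains, spike_rate, numeric(1), onset = onset, offset = offset))
}
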