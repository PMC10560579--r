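#' Discrete prolate spheroidal (Slepian) sequences
#'
#' Computes the first `k` Slepian tapers of length `n` with time-bandwidth
#' product `nw`, via the eigenvectors of the classical symmetric tridiagonal
#' matrix, which shares eigenvectors with the concentration problem. Tapers
#' are normalized to unit energy and their leading sign fixed so identical
#' inputs always yield identical tapers. Results are cached per
#' `(n, nw, k)`.
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product (half-bandwidth parameter).
#' @param k number of tapers.
#' @return `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  if (k >= n) stop_arg("need more samples (%d) than tapers (%d)", n, k)
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.nb_cache[[key]])) return(.nb_cache[[key]])
  W <- nw / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  diag(A) <- d
  A[cbind(1:(n - 1), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1))] <- e
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j] / sqrt(sum(V[, j]^2))
    # symmetric tapers: positive mean; antisymmetric: positive initial slope
    if (j %% 2 == 1) { if (sum(v) < 0) v <- -v } else if (v[2] < v[1]) v <- -v
    V[, j] <- v
  }
  .nb_cache[[key]] <- V
  V
}

# anti-aliased decimation to at most `target_fs`; spectra of interest live
# below 50 Hz so working at <= 1 kS/s loses nothing and keeps taper
# computation desk-scale
decimate_for_psd <- function(x, fs, target_fs = 1000) {
  if (fs <= target_fs) return(list(x = x, fs = fs))
  q <- ceiling(fs / target_fs)
  fs_new <- fs / q
  bf <- signal::butter(6, 0.8 * (fs_new / 2) / (fs / 2), type = "low")
  xf <- as.numeric(signal::filtfilt(bf, x))
  list(x = xf[seq(1, length(xf), by = q)], fs = fs_new)
}

#' Multitaper power spectral density
#'
#' Multitaper PSD with half-bandwidth parameter `nw = 3` and the first five
#' Slepian sequences, estimated on 1 s windows advanced by 0.1 s and
#' averaged. Eigenspectra are combined with unit weights (adaptive
#' weighting available via `adaptive = TRUE`). Segments shorter than one
#' window are estimated with a single full-length window (with a warning);
#' segments shorter than 0.2 s are an error. Signals sampled above 1 kS/s
#' are decimated (anti-aliased) to at most 1 kS/s first.
#'
#' @param x numeric signal, microvolts.
#' @param fs sampling rate, samples/second.
#' @param window_s analysis window, seconds (default 1).
#' @param step_s window step, seconds (default 0.1).
#' @param nw half-bandwidth parameter (default 3).
#' @param k number of tapers (default 5).
#' @param adaptive use Thomson adaptive eigenspectrum weights instead of
#'   unit weights (default FALSE).
#' @return object of class `psd`: list with `freqs` (Hz), `power`
#'   (microvolts^2/Hz, one-sided), `params`, `n_windows`.
#' @export
multitaper_psd <- function(x, fs, window_s = 1, step_s = 0.1, nw = 3, k = 5,
                           adaptive = FALSE) {
  if (length(x) / fs < 0.2)
    stop_arg("segment of %.3f s is too short for spectral estimation (minimum 0.2 s)",
             length(x) / fs)
  dec <- decimate_for_psd(x, fs)
  x <- dec$x; fs <- dec$fs
  w <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  if (length(x) < w) {
    warning(sprintf("segment (%.2f s) shorter than the %g s analysis window; using a single window",
                    length(x) / fs, window_s))
    w <- length(x)
  }
  starts <- seq(1L, length(x) - w + 1L, by = step)
  V <- dpss_tapers(w, nw, k)
  nfft <- next_pow2(w)
  nfreq <- nfft %/% 2 + 1
  freqs <- (0:(nfreq - 1)) * fs / nfft
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + w - 1L)]
    tap <- V * seg                       # n x k tapered copies
    tapz <- rbind(tap, matrix(0, nfft - w, k))
    eig <- Mod(stats::mvfft(tapz))^2 / fs   # eigenspectra, two-sided density
    eig <- eig[seq_len(nfreq), , drop = FALSE]
    Sk <- if (adaptive) adaptive_combine(eig, seg, fs) else rowMeans(eig)
    acc <- acc + Sk
  }
  pw <- acc / length(starts)
  # one-sided: double interior bins
  if (nfft %% 2 == 0) pw[2:(nfreq - 1)] <- 2 * pw[2:(nfreq - 1)]
  else pw[2:nfreq] <- 2 * pw[2:nfreq]
  structure(list(freqs = freqs, power = pw,
                 params = list(window_s = window_s, step_s = step_s, nw = nw,
                               k = k, fs = fs, adaptive = adaptive),
                 n_windows = length(starts)),
            class = "psd")
}

# Thomson adaptive weighting for one window's eigenspectra
adaptive_combine <- function(eig, seg, fs) {
  sig2 <- stats::var(seg) / fs
  S <- rowMeans(eig[, 1:2, drop = FALSE])
  lam <- rep(0.999, ncol(eig))  # high-concentration approximation
  for (it in 1:20) {
    d <- outer(S, lam) / (outer(S, lam) + sig2 * (1 - rep(lam, each = length(S))))
    w <- d^2 %*% diag(lam, ncol(eig))
    Snew <- rowSums(w * eig) / rowSums(w)
    if (max(abs(Snew - S) / pmax(Snew, 1e-300)) < 1e-6) break
    S <- Snew
  }
  S
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins, 0-%.1f Hz, %d window(s)\n",
              length(x$freqs), max(x$freqs), x$n_windows))
  invisible(x)
}

#' Baseline (non-bursting) power spectrum
#'
#' Mean multitaper PSD across all periods of the recording not covered by
#' burst events and exceeding 1 s in duration; each qualifying gap is
#' weighted by its number of analysis windows. This is the denominator of
#' the baseline normalization applied to every event spectrum.
#'
#' @param x LFP signal, microvolts.
#' @param fs sampling rate.
#' @param events data frame of burst events (`onset_s`, `offset_s`), or
#'   NULL/empty for a recording with no detected events.
#' @param min_gap_s minimum quiet-period duration to include (default 1 s).
#' @param ... passed to [multitaper_psd()].
#' @return `psd` object.
#' @export
baseline_psd <- function(x, fs, events = NULL, min_gap_s = 1, ...) {
  total_s <- length(x) / fs
  cover <- interval_union(events_to_intervals(events))
  gaps <- matrix(numeric(0), ncol = 2)
  t <- 0
  if (nrow(cover)) {
    for (i in seq_len(nrow(cover))) {
      if (cover[i, 1] - t > min_gap_s) gaps <- rbind(gaps, c(t, cover[i, 1]))
      t <- max(t, cover[i, 2])
    }
  }
  if (total_s - t > min_gap_s) gaps <- rbind(gaps, c(t, total_s))
  if (nrow(gaps) == 0)
    stop_arg(paste0("no non-bursting period exceeding %g s available for the baseline PSD; ",
                    "supply a fallback baseline recording"), min_gap_s)
  acc <- NULL; wsum <- 0
  for (i in seq_len(nrow(gaps))) {
    seg <- slice_signal(x, fs, gaps[i, 1], gaps[i, 2])
    p <- multitaper_psd(seg, fs, ...)
    if (is.null(acc)) {
      acc <- p$power * p$n_windows
      ref <- p
    } else {
      acc <- acc + stats::approx(p$freqs, p$power, xout = ref$freqs, rule = 2)$y * p$n_windows
    }
    wsum <- wsum + p$n_windows
  }
  ref$power <- acc / wsum
  ref$n_windows <- wsum
  ref
}

#' Baseline-normalize a power spectrum
#'
#' Pointwise ratio P/P0 of a segment PSD to the baseline PSD. Grids are
#' matched by linear interpolation of the baseline; baseline bins below
#' `floor_power` are floored before division to avoid infinities, and the
#' affected bins are reported.
#'
#' @param psd `psd` object for the segment.
#' @param baseline `psd` object from [baseline_psd()].
#' @param floor_power numeric floor for baseline bins (default 1e-12).
#' @return object of class `normalized_psd`: list with `freqs`,
#'   `relative_power`, `floored_bins`.
#' @export
normalize_psd <- function(psd, baseline, floor_power = 1e-12) {
  p0 <- stats::approx(baseline$freqs, baseline$power, xout = psd$freqs, rule = 2)$y
  floored <- which(p0 < floor_power)
  p0 <- pmax(p0, floor_power)
  structure(list(freqs = psd$freqs, relative_power = psd$power / p0,
                 floored_bins = floored),
            class = "normalized_psd")
}

#' Fractional band power of a normalized spectrum
#'
#' Integral of the normalized spectrum over `band` divided by its integral
#' over `total` (1-50 Hz by default): the relative theta-alpha (4-16 Hz)
#' and beta-low gamma (16-40 Hz) power features.
#'
#' @param npsd `normalized_psd` (or `psd`) object.
#' @param band two-element numeric, Hz; must lie within `total`.
#' @param total reference band, Hz (default `c(1, 50)`).
#' @return dimensionless fraction in \[0, 1\].
#' @export
band_fraction <- function(npsd, band, total = c(1, 50)) {
  if (band[1] < total[1] || band[2] > total[2])
    stop_arg("band [%g, %g] Hz must lie within the total band [%g, %g] Hz",
             band[1], band[2], total[1], total[2])
  y <- npsd$relative_power %||% npsd$power
  band_integral(npsd$freqs, y, band[1], band[2]) /
    band_integral(npsd$freqs, y, total[1], total[2])
}
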