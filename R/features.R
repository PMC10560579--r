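# local minima of `y` whose topographic prominence exceeds `min_prom`;
# returns indices. Prominence of a trough = depth below the lower of the
# two saddle maxima separating it from deeper troughs (computed on -y as
# standard peak prominence).
prominent_troughs <- function(y, min_prom) {
  z <- -y
  n <- length(z)
  if (n < 3) return(integer(0))
  pk <- which(diff(sign(diff(z))) < 0) + 1L
  keep <- logical(length(pk))
  for (ii in seq_along(pk)) {
    i <- pk[ii]
    # walk left/right until a sample higher than z[i]; track the minimum
    lmin <- z[i]; j <- i
    while (j > 1 && z[j] <= z[i]) { j <- j - 1; lmin <- min(lmin, z[j]) }
    lbase <- if (z[j] > z[i]) lmin else min(z[1:i])
    rmin <- z[i]; j <- i
    while (j < n && z[j] <= z[i]) { j <- j + 1; rmin <- min(rmin, z[j]) }
    rbase <- if (z[j] > z[i]) rmin else min(z[i:n])
    prom <- z[i] - max(lbase, rbase)
    keep[ii] <- prom > min_prom
  }
  pk[keep]
}

#' Nine-dimensional feature vector of a burst event
#'
#' Computes the per-event features used for unsupervised classification:
#' \describe{
#'   \item{duration}{offset - onset, seconds.}
#'   \item{negative_peak}{minimum deflection of the 4-100 Hz signal,
#'     microvolts.}
#'   \item{max_rms}{maximum RMS over the event's 200 ms chunks, microvolts.}
#'   \item{flatness}{min(RMS)/max(RMS) over those chunks, in (0, 1].}
#'   \item{max_slope}{maximum absolute sample-to-sample difference after
#'     downsampling the event to 500 S/s, microvolts per sample.}
#'   \item{iti}{mean inter-trough interval, seconds; troughs are local
#'     minima whose prominence exceeds half the event RMS. With fewer than
#'     two qualifying troughs the feature is set to the event duration and
#'     flagged (keeps the feature matrix rectangular).}
#'   \item{rel_theta_alpha}{fraction of baseline-normalized 1-50 Hz power
#'     in 4-16 Hz.}
#'   \item{rel_beta_low_gamma}{fraction in 16-40 Hz.}
#'   \item{spike_rate}{spikes per second over the event.}
#' }
#'
#' @param event one-row data frame (`onset_s`, `offset_s`).
#' @param x LFP signal band-passed 4-100 Hz, microvolts.
#' @param fs sampling rate.
#' @param spike_times spike times for the event's region, seconds.
#' @param baseline `psd` object from [baseline_psd()].
#' @return named numeric vector of the nine features, with attribute
#'   `iti_defaulted`.
#' @export
compute_features <- function(event, x, fs, spike_times, baseline) {
  seg <- slice_signal(x, fs, event$onset_s, event$offset_s)
  dur <- event$offset_s - event$onset_s
  chunks <- windowed_rms(seg, fs, 0.2)
  ev_rms <- sqrt(mean(seg^2))
  # slope on the 500 S/s downsampled event
  t_orig <- seq_along(seg) / fs
  t_ds <- seq(1 / 500, dur, by = 1 / 500)
  ds <- stats::approx(t_orig, seg, xout = t_ds, rule = 2)$y
  max_slope <- if (length(ds) > 1) max(abs(diff(ds))) else 0
  troughs <- prominent_troughs(seg, ev_rms / 2)
  iti_defaulted <- length(troughs) < 2
  iti <- if (iti_defaulted) dur else mean(diff(troughs)) / fs
  npsd <- normalize_psd(multitaper_psd(seg, fs), baseline)
  out <- c(duration = dur,
           negative_peak = min(seg),
           max_rms = max(chunks),
           flatness = min(chunks) / max(chunks),
           max_slope = max_slope,
           iti = iti,
           rel_theta_alpha = band_fraction(npsd, c(4, 16)),
           rel_beta_low_gamma = band_fraction(npsd, c(16, 40)),
           spike_rate = spike_rate(spike_times, event$onset_s, event$offset_s))
  attr(out, "iti_defaulted") <- iti_defaulted
  out
}

#' Feature matrix for a set of events
#'
#' Applies [compute_features()] to every retained event.
#'
#' @param events data frame of retained events.
#' @param x 4-100 Hz filtered LFP.
#' @param fs sampling rate.
#' @param spike_times region spike times, seconds.
#' @param baseline baseline `psd`.
#' @return events x 9 numeric matrix with feature names as columns.
#' @export
burst_feature_matrix <- function(events, x, fs, spike_times, baseline) {
  out <- t(vapply(seq_len(nrow(events)), function(i) {
    as.numeric(compute_features(events[i, ], x, fs, spike_times, baseline))
  }, numeric(9)))
  colnames(out) <- c("duration", "negative_peak", "max_rms", "flatness",
                     "max_slope", "iti", "rel_theta_alpha",
                     "rel_beta_low_gamma", "spike_rate")
  rownames(out) <- events$event_id
  out
}

#' Normalize features and embed with PCA
#'
#' Features are z-scored (min-max scaling available via `method`) and
#' projected onto their first principal components. Constant features are
#' dropped with a warning. Component signs follow a deterministic
#' convention: the loading of largest magnitude in each component is made
#' positive, so embeddings are reproducible across runs.
#'
#' @param feats events x features numeric matrix.
#' @param n_components number of components to keep (default 3).
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return list with `scores` (events x n_components), `loadings`,
#'   `explained_var` (fraction per kept component), `dropped` (names of
#'   constant features removed).
#' @export
normalize_and_embed <- function(feats, n_components = 3,
                                method = c("zscore", "minmax")) {
  method <- match.arg(method)
  if (nrow(feats) < n_components + 1)
    stop_arg("need at least %d events for a %d-component embedding (got %d)",
             n_components + 1, n_components, nrow(feats))
  sds <- apply(feats, 2, stats::sd)
  dropped <- colnames(feats)[sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping constant feature(s): %s", paste(dropped, collapse = ", ")))
    feats <- feats[, sds > 0, drop = FALSE]
  }
  z <- if (method == "zscore") scale(feats)
       else apply(feats, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = rot,
       explained_var = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       dropped = dropped)
}
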