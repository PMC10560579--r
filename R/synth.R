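#' Synthetic recording configuration
#'
#' Parameters of the ground-truth generator. Defaults emulate the burst
#' phenomenology of developing cortex/striatum/thalamus: 1/f background
#' noise, spindle bursts (SB) with dominant 4-16 Hz power lasting ~1.3 s,
#' longer (~4 s) and larger nested gamma spindle bursts (NGB) carrying an
#' additional 16-40 Hz component amplitude-modulated by the spindle
#' envelope, a few events per minute, cross-regional co-occurrence with
#' configurable signed propagation lags of tens of milliseconds, shared
#' band-limited components controlling coherence, and spike trains
#' phase-coupled to the burst oscillation.
#'
#' Propagation lags and co-occurrence are defined relative to the first
#' listed region (the reference): `lag_ms` is the onset time of the
#' propagated event minus the onset of its reference-region partner, so a
#' positive lag means the reference region leads. `lag_ms` and
#' `cooccur_prob` may be single numbers (applied to every pair) or named
#' vectors keyed `"<reference>-><region>"`.
#'
#' @param duration_s recording length, seconds.
#' @param fs sampling rate, samples/second. Must be at least 2.5 times the
#'   highest synthesized LFP frequency.
#' @param regions character vector of region names; the first is the
#'   propagation reference.
#' @param sb_per_min,ngb_per_min per-region event incidence, events/minute.
#' @param sb_dur_mean_s,ngb_dur_mean_s mean event durations, seconds
#'   (lognormal; SD on the log scale `sb_dur_sdlog`, `ngb_dur_sdlog`).
#' @param sb_dur_sdlog,ngb_dur_sdlog lognormal shape of the duration
#'   distributions.
#' @param sb_carrier_hz SB carrier frequency, Hz (within 4-16).
#' @param ngb_nested_hz NGB nested oscillation frequency, Hz (within 16-40).
#' @param carrier_linewidth_hz spectral half-width of the stochastic
#'   phase-walk carriers, Hz.
#' @param nested_gain amplitude of the nested component relative to the
#'   spindle component of an NGB.
#' @param sb_amp_uv,ngb_amp_uv peak event amplitudes, microvolts.
#' @param noise_exponent background noise spectral exponent alpha in
#'   1/f^alpha.
#' @param noise_rms_uv background noise RMS, microvolts.
#' @param cooccur_prob probability that a reference-region event propagates
#'   to each other region, in \[0,1\].
#' @param lag_ms signed propagation lag, milliseconds.
#' @param shared_gain fraction (amplitude) of a propagated event's waveform
#'   shared with its partner, in \[0,1\]; controls band-limited coherence.
#' @param spike_base_rate_hz background spike rate per region, Hz.
#' @param burst_rate_gain multiplicative spike-rate increase during bursts.
#' @param phase_coupling depth of spike-phase coupling to the burst
#'   oscillation, in \[0,1\].
#' @param mua_noise_rms_uv,spike_amp_uv MUA channel noise floor and spike
#'   template amplitude, microvolts.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 600, fs = 10000,
                         regions = c("cortex", "striatum", "thalamus"),
                         sb_per_min = 4, ngb_per_min = 2,
                         sb_dur_mean_s = 1.3, sb_dur_sdlog = 0.35,
                         ngb_dur_mean_s = 4, ngb_dur_sdlog = 0.25,
                         sb_carrier_hz = 8, ngb_nested_hz = 25,
                         carrier_linewidth_hz = 1.5, nested_gain = 0.8,
                         sb_amp_uv = 200, ngb_amp_uv = 400,
                         noise_exponent = 1, noise_rms_uv = 30,
                         cooccur_prob = 0.5, lag_ms = 20, shared_gain = 0.8,
                         spike_base_rate_hz = 1, burst_rate_gain = 8,
                         phase_coupling = 0.6,
                         mua_noise_rms_uv = 3, spike_amp_uv = 40,
                         seed = 1L) {
  cfg <- as.list(environment())
  check_scalar(duration_s, "duration_s", min = 1)
  check_scalar(fs, "fs", min = 1)
  if (length(regions) < 1 || any(!nzchar(regions)))
    stop_arg("configuration error: field 'regions' must be non-empty names")
  for (f in c("sb_per_min", "ngb_per_min"))
    check_scalar(cfg[[f]], f, min = 0)
  for (f in c("cooccur_prob", "shared_gain", "phase_coupling"))
    for (v in cfg[[f]]) check_scalar(v, f, min = 0, max = 1)
  if (sb_carrier_hz < 4 || sb_carrier_hz > 16)
    stop_arg("configuration error: field 'sb_carrier_hz' must lie in 4-16 Hz")
  if (ngb_nested_hz < 16 || ngb_nested_hz > 40)
    stop_arg("configuration error: field 'ngb_nested_hz' must lie in 16-40 Hz")
  check_scalar(spike_base_rate_hz, "spike_base_rate_hz", min = 0)
  if (fs < 2.5 * ngb_nested_hz)
    stop_arg("configuration error: fs = %g must be at least 2.5 x the highest synthesized frequency (%g Hz)",
             fs, ngb_nested_hz)
  check_scalar(seed, "seed", min = 0, max = 2^31 - 1)
  structure(cfg, class = "synth_config")
}

pair_param <- function(p, key) {
  if (length(p) == 1 && is.null(names(p))) return(unname(p))
  if (!is.null(names(p)) && key %in% names(p)) return(unname(p[[key]]))
  unname(p[[1]])
}

# 1/f^alpha Gaussian noise with target RMS, synthesized in the frequency
# domain; uses the current RNG state
pink_noise <- function(n, fs, exponent = 1, rms = 1) {
  nfft <- next_pow2(n)
  f <- c(1, seq_len(nfft / 2)) * fs / nfft   # avoid f = 0 blowup
  mag <- f^(-exponent / 2)
  ph <- stats::runif(nfft / 2 + 1, 0, 2 * pi)
  half <- mag * exp(1i * ph)
  half[1] <- 0
  spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x * rms / stats::sd(x)
}

# narrowband stochastic oscillation: unit-RMS cosine carrier whose phase
# performs a Brownian walk, giving a Lorentzian line of half-width
# `linewidth_hz` centered at f0
phase_walk_carrier <- function(n, fs, f0, linewidth_hz = 1.5) {
  dphi <- stats::rnorm(n, mean = 2 * pi * f0 / fs,
                       sd = sqrt(4 * pi * linewidth_hz / fs))
  x <- cos(cumsum(dphi))
  x / sqrt(mean(x^2))
}

#' Synthesize a single burst waveform
#'
#' An SB is a narrowband stochastic oscillation at the carrier frequency
#' under a Hann amplitude envelope (smooth rise/fall avoids filter-ringing
#' confounds in detection tests). An NGB adds a faster component at the
#' nested frequency whose amplitude is modulated by the phase of the
#' spindle-frequency component, i.e. gamma nested in the spindle envelope.
#' `amplitude` scales the waveform so its envelope peak equals roughly that
#' many microvolts.
#'
#' @param kind `"SB"` or `"NGB"`.
#' @param duration_s burst length, seconds (> 0).
#' @param fs sampling rate.
#' @param carrier_hz spindle-band carrier, Hz.
#' @param nested_hz nested-band frequency, Hz (NGB only).
#' @param amplitude peak amplitude, microvolts.
#' @param nested_gain relative amplitude of the nested component.
#' @param linewidth_hz carrier linewidth, Hz.
#' @param seed optional integer seed; NULL uses the current RNG state.
#' @return numeric waveform of length `round(duration_s * fs)`, microvolts.
#' @export
synthesize_burst <- function(kind = c("SB", "NGB"), duration_s, fs,
                             carrier_hz = 8, nested_hz = 25, amplitude = 200,
                             nested_gain = 0.8, linewidth_hz = 1.5,
                             seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_arg("burst duration must be positive (got %s)", format(duration_s))
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  lo <- phase_walk_carrier(n, fs, carrier_hz, linewidth_hz)
  w <- lo
  if (kind == "NGB") {
    hi <- phase_walk_carrier(n, fs, nested_hz, linewidth_hz)
    # nested amplitude follows the spindle cycle: max gamma on the spindle peak
    menv <- (1 + lo / max(abs(lo))) / 2
    w <- lo + nested_gain * menv * hi
  }
  # Hann-shaped rise/fall ramps around a sustained plateau, so the event
  # holds its nominal amplitude over its nominal span (a full bell would
  # leave edge cycles far below threshold and misalign truth spans)
  ramp <- min(round(0.25 * fs), floor(n / 4))
  env <- rep(1, n)
  if (ramp > 0) {
    up <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
    env[seq_len(ramp)] <- up
    env[n + 1 - seq_len(ramp)] <- up
  }
  w <- w * env
  if (max(abs(w)) == 0) return(w)
  w * amplitude / max(abs(w))
}

#' Phase-coupled spike train from an LFP segment
#'
#' Inhomogeneous Poisson spike train whose intensity is modulated by the
#' instantaneous phase of the LFP oscillation:
#' `rate(t) = base_rate * (1 + coupling * cos(phase(t)))`, where phase is
#' taken from the analytic signal. `coupling = 0` gives a homogeneous
#' Poisson train at `base_rate`. Sampling is by thinning.
#'
#' @param lfp_segment numeric oscillation the spikes couple to.
#' @param fs sampling rate of the segment.
#' @param base_rate mean rate, Hz (>= 0).
#' @param coupling modulation depth in \[0,1\].
#' @param t0 time of the first sample, seconds (spike times are absolute).
#' @param seed optional integer seed.
#' @return numeric vector of spike times, seconds, strictly increasing.
#' @export
generate_spike_train <- function(lfp_segment, fs, base_rate, coupling = 0,
                                 t0 = 0, seed = NULL) {
  if (base_rate < 0) stop_arg("base_rate must be >= 0")
  if (coupling < 0 || coupling > 1)
    stop_arg("coupling must lie in [0, 1] (got %g)", coupling)
  if (!is.null(seed)) set.seed(seed)
  dur <- length(lfp_segment) / fs
  if (base_rate == 0 || dur <= 0) return(numeric(0))
  lambda_max <- base_rate * (1 + coupling)
  n_cand <- stats::rpois(1, lambda_max * dur)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, dur))
  if (coupling == 0) return(cand + t0)
  phase <- Arg(analytic_signal(lfp_segment))
  ph <- phase[pmin(length(phase), floor(cand * fs) + 1)]
  lam <- base_rate * (1 + coupling * cos(ph))
  keep <- stats::runif(n_cand) < lam / lambda_max
  cand[keep] + t0
}

# biphasic extracellular spike template, ~1 ms, dominant negative phase
spike_template <- function(fs, amp_uv = 40) {
  t <- seq(0, 0.001, by = 1 / fs)
  w <- -exp(-((t - 0.00035) / 0.00012)^2) + 0.45 * exp(-((t - 0.00065) / 0.00018)^2)
  w * amp_uv / max(abs(w))
}

#' Generate a ground-truth-annotated multi-region recording
#'
#' Builds one LFP and one MUA channel per configured region. Events are
#' placed by a Poisson process thinned to forbid same-region overlap
#' (overlapping truth events would make detection recall ill-defined).
#' Each reference-region event propagates to every other region with the
#' configured probability; a propagated event starts `lag_ms` later and its
#' waveform mixes the reference waveform (amplitude fraction `shared_gain`)
#' with an independent oscillation of the same kind, so co-occurring pairs
#' are band-limited coherent with the imposed lag. Spikes are a homogeneous
#' background train plus phase-coupled bursts of spiking during each event;
#' the MUA channel is noise plus a biphasic ~1 ms template at every spike
#' time.
#'
#' @param config `synth_config` object.
#' @return list with components `recording` (a [new_recording()] object) and
#'   `truth`: `events` (event_id, region, kind, onset_s, offset_s, amp_uv),
#'   `pairs` (event_id_a = reference event, event_id_b = propagated event,
#'   lag_ms = onset_b - onset_a in ms) and `spikes` (region, time_s).
#' @export
generate_recording <- function(config) {
  if (!inherits(config, "synth_config"))
    stop_arg("config must be created by synth_config()")
  cfg <- config
  set.seed(as.integer(cfg$seed))
  fs <- cfg$fs; dur <- cfg$duration_s
  n <- round(dur * fs)
  regions <- cfg$regions
  nr <- length(regions)

  events <- data.frame(event_id = integer(0), region = character(0),
                       kind = character(0), onset_s = numeric(0),
                       offset_s = numeric(0), amp_uv = numeric(0))
  pairs <- data.frame(event_id_a = integer(0), event_id_b = integer(0),
                      region_a = character(0), region_b = character(0),
                      lag_ms = numeric(0))
  waves <- list()   # per event: waveform vector
  next_id <- 1L

  draw_events <- function(region, kind, rate_per_min, occupied) {
    mean_s <- if (kind == "SB") cfg$sb_dur_mean_s else cfg$ngb_dur_mean_s
    sdlog <- if (kind == "SB") cfg$sb_dur_sdlog else cfg$ngb_dur_sdlog
    amp0 <- if (kind == "SB") cfg$sb_amp_uv else cfg$ngb_amp_uv
    m <- stats::rpois(1, rate_per_min * dur / 60)
    out <- NULL
    for (i in seq_len(m)) {
      d <- stats::rlnorm(1, log(mean_s) - sdlog^2 / 2, sdlog)
      d <- min(max(d, 0.4), 15)
      on <- stats::runif(1, 0.5, max(0.6, dur - d - 0.5))
      out <- rbind(out, data.frame(kind = kind, onset_s = on, offset_s = on + d,
                                   amp_uv = amp0 * stats::rlnorm(1, 0, 0.15)))
    }
    out
  }

  place <- function(cand, occupied, margin = 0.3) {
    # thin candidate events that collide with already-placed ones
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      iv <- c(cand$onset_s[i] - margin, cand$offset_s[i] + margin)
      hit <- nrow(occupied) > 0 &&
        any(occupied[, 1] < iv[2] & occupied[, 2] > iv[1])
      if (!hit) {
        occupied <- rbind(occupied, c(cand$onset_s[i], cand$offset_s[i]))
        keep[i] <- TRUE
      }
    }
    list(keep = keep, occupied = occupied)
  }

  occupied <- lapply(seq_len(nr), function(i) matrix(numeric(0), ncol = 2))

  # reference region events
  ref_cand <- rbind(draw_events(regions[1], "SB", cfg$sb_per_min),
                    draw_events(regions[1], "NGB", cfg$ngb_per_min))
  if (!is.null(ref_cand) && nrow(ref_cand)) {
    ref_cand <- ref_cand[order(ref_cand$onset_s), , drop = FALSE]
    pl <- place(ref_cand, occupied[[1]])
    occupied[[1]] <- pl$occupied
    ref_cand <- ref_cand[pl$keep, , drop = FALSE]
  }
  ref_ids <- integer(0)
  if (!is.null(ref_cand)) for (i in seq_len(nrow(ref_cand))) {
    ev <- ref_cand[i, ]
    w <- synthesize_burst(ev$kind, ev$offset_s - ev$onset_s, fs,
                          carrier_hz = cfg$sb_carrier_hz,
                          nested_hz = cfg$ngb_nested_hz,
                          amplitude = ev$amp_uv,
                          nested_gain = cfg$nested_gain,
                          linewidth_hz = cfg$carrier_linewidth_hz)
    events <- rbind(events, data.frame(event_id = next_id, region = regions[1],
                                       kind = ev$kind, onset_s = ev$onset_s,
                                       offset_s = ev$offset_s, amp_uv = ev$amp_uv))
    waves[[next_id]] <- w
    ref_ids <- c(ref_ids, next_id)
    next_id <- next_id + 1L
  }

  # propagated + independent events in the other regions
  for (j in seq_len(nr)[-1]) {
    key <- paste0(regions[1], "->", regions[j])
    p <- pair_param(cfg$cooccur_prob, key)
    lag <- pair_param(cfg$lag_ms, key)
    g <- pair_param(cfg$shared_gain, key)
    for (id in ref_ids) {
      if (stats::rbinom(1, 1, p) == 0) next
      ev <- events[events$event_id == id, ]
      on_b <- ev$onset_s + lag / 1000
      off_b <- ev$offset_s + lag / 1000
      if (on_b < 0 || off_b > dur) next
      pl <- place(data.frame(onset_s = on_b, offset_s = off_b), occupied[[j]])
      if (!pl$keep[1]) next
      occupied[[j]] <- pl$occupied
      amp_b <- ev$amp_uv * stats::rlnorm(1, 0, 0.1)
      indep <- synthesize_burst(ev$kind, off_b - on_b, fs,
                                carrier_hz = cfg$sb_carrier_hz,
                                nested_hz = cfg$ngb_nested_hz,
                                amplitude = 1,
                                nested_gain = cfg$nested_gain,
                                linewidth_hz = cfg$carrier_linewidth_hz)
      shared <- waves[[id]] / max(abs(waves[[id]]))
      m <- min(length(shared), length(indep))
      wb <- g * shared[seq_len(m)] + sqrt(1 - g^2) * indep[seq_len(m)]
      wb <- wb * amp_b / max(abs(wb))
      events <- rbind(events, data.frame(event_id = next_id, region = regions[j],
                                         kind = ev$kind, onset_s = on_b,
                                         offset_s = off_b, amp_uv = amp_b))
      waves[[next_id]] <- wb
      pairs <- rbind(pairs, data.frame(event_id_a = id, event_id_b = next_id,
                                       region_a = regions[1], region_b = regions[j],
                                       lag_ms = lag))
      next_id <- next_id + 1L
    }
    # independent events keep the region's total incidence near nominal
    for (kind in c("SB", "NGB")) {
      rate <- if (kind == "SB") cfg$sb_per_min else cfg$ngb_per_min
      resid <- max(0, rate * (1 - p))
      cand <- draw_events(regions[j], kind, resid)
      if (is.null(cand) || nrow(cand) == 0) next
      pl <- place(cand, occupied[[j]])
      occupied[[j]] <- pl$occupied
      cand <- cand[pl$keep, , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        ev <- cand[i, ]
        w <- synthesize_burst(ev$kind, ev$offset_s - ev$onset_s, fs,
                              carrier_hz = cfg$sb_carrier_hz,
                              nested_hz = cfg$ngb_nested_hz,
                              amplitude = ev$amp_uv,
                              nested_gain = cfg$nested_gain,
                              linewidth_hz = cfg$carrier_linewidth_hz)
        events <- rbind(events, data.frame(event_id = next_id, region = regions[j],
                                           kind = ev$kind, onset_s = ev$onset_s,
                                           offset_s = ev$offset_s, amp_uv = ev$amp_uv))
        waves[[next_id]] <- w
        next_id <- next_id + 1L
      }
    }
  }

  # assemble channels
  samples <- matrix(0, nrow = 2 * nr, ncol = n)
  chans <- data.frame(region = rep(regions, each = 2),
                      kind = rep(c("lfp", "mua"), nr),
                      depth = rep(seq_len(nr), each = 2))
  spikes <- data.frame(region = character(0), time_s = numeric(0))
  tmpl <- spike_template(fs, cfg$spike_amp_uv)

  for (j in seq_len(nr)) {
    lfp <- pink_noise(n, fs, cfg$noise_exponent, cfg$noise_rms_uv)
    burst_sum <- numeric(n)
    evr <- events[events$region == regions[j], , drop = FALSE]
    for (i in seq_len(nrow(evr))) {
      i0 <- floor(evr$onset_s[i] * fs) + 1L
      w <- waves[[evr$event_id[i]]]
      i1 <- min(n, i0 + length(w) - 1L)
      burst_sum[i0:i1] <- burst_sum[i0:i1] + w[seq_len(i1 - i0 + 1L)]
    }
    lfp <- lfp + burst_sum
    # spikes: homogeneous background + phase-coupled bursts
    st <- generate_spike_train(numeric(n), fs, cfg$spike_base_rate_hz, 0)
    for (i in seq_len(nrow(evr))) {
      w <- waves[[evr$event_id[i]]]
      st <- c(st, generate_spike_train(
        w, fs, cfg$spike_base_rate_hz * cfg$burst_rate_gain,
        cfg$phase_coupling, t0 = evr$onset_s[i]))
    }
    st <- sort(st[st >= 0 & st < dur])
    mua <- stats::rnorm(n, 0, cfg$mua_noise_rms_uv)
    for (t in st) {
      i0 <- floor(t * fs) + 1L
      i1 <- min(n, i0 + length(tmpl) - 1L)
      mua[i0:i1] <- mua[i0:i1] + tmpl[seq_len(i1 - i0 + 1L)] *
        stats::rlnorm(1, 0, 0.2)
    }
    samples[2 * j - 1, ] <- lfp
    samples[2 * j, ] <- mua
    if (length(st))
      spikes <- rbind(spikes, data.frame(region = regions[j], time_s = st))
  }

  rownames(events) <- NULL
  list(recording = new_recording(samples, fs, chans),
       truth = list(events = events, pairs = pairs, spikes = spikes))
}
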