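# netbursts

Detection, classification and cross-regional analysis of transient network
bursts in multichannel extracellular recordings from the developing brain.

In the first two postnatal weeks, cortex, striatum and thalamus are not yet
continuously active: their local field potentials (LFP) show brief
oscillatory bursts separated by relative silence. Two burst types dominate
this period: **spindle bursts (SB)**, with power concentrated in the
theta–alpha range (~4–16 Hz), and **nested gamma spindle bursts (NGB)**,
longer and larger events carrying an additional beta–low-gamma (~16–40 Hz)
component nested in the spindle envelope. Because these events co-occur
across regions with millisecond-scale onset lags, they are the substrate
for asking which structure drives which during development. `netbursts`
implements that full analysis as a tested, seedable R pipeline, together
with a synthetic-data generator that provides ground truth for every stage.

## What the pipeline computes

1. **Burst detection by RMS thresholding.** The 4–100 Hz LFP is reduced to
   RMS values over non-overlapping 200 ms windows; a Gaussian
   `A·exp(−(x−μ)²/2σ²)` is least-squares fitted to the RMS histogram (with
   the mean capped at 50 µV so the burst mode cannot drag the fit) and the
   detection threshold set at `μ + 3σ`. Consecutive supra-threshold windows
   merge into events; events shorter than 0.2 s or longer than 20 s, with
   fewer than five oscillation peaks above their mean RMS, or with mean RMS
   above 1000 µV (movement artifacts) are rejected. An independent
   envelope-threshold detector and a temporal-overlap comparison are
   included for cross-validation.
2. **Unsupervised SB/NGB classification.** Nine per-event features
   (duration, negative peak, max RMS, flatness, max slope at 500 S/s, mean
   inter-trough interval, relative 4–16 Hz power, relative 16–40 Hz power,
   spike rate) are z-scored, embedded with PCA, and the first three
   components clustered by fuzzy c-means. The cluster count is chosen by
   the fuzzy partition coefficient (FPC); events whose maximum membership
   does not exceed 0.6 stay unclassified (UC); the cluster with more
   beta–low-gamma power is NGB.
3. **Spectra.** Multitaper PSDs (1 s windows, 0.1 s step, half-bandwidth
   NW = 3, five Slepian tapers) normalized by the mean PSD of all
   non-bursting periods longer than 1 s (`P/P₀`).
4. **Cross-regional interactions.** Bursts with onsets within 0.5 s are
   co-occurring pairs. Welch cross-spectral coherence (0.5 s windows, no
   overlap) is compared against the 95th percentile of a 1000-fold
   pair-shuffle null; pairs with mean coherence above 0.8 are discarded as
   artifacts. Imaginary coherence and spike-field coherence (2 ms-binned
   trains vs 4–80 Hz LFP, spike-shuffle null) are also available. Lags are
   estimated as the peak of the normalized cross-correlation (±50 ms) of
   AR-pre-whitened band-passed signals (4–16 or 16–40 Hz); |lag| < 20 ms is
   flagged putative monosynaptic. Spike-train lags use 2 ms Gaussian
   smoothing and a ±10 ms window with a one-sample t-test across pairs.
5. **Statistics.** A distance-based multivariate permutation F-test,

   F = SS_A / SS_W,  SS_A = Σᵢ nᵢ‖Ȳ − Ȳᵢ‖² / (K−1),
   SS_W = Σᵢ Σⱼ ‖Ȳᵢ − Y_ij‖² / (N−K),

   with significance from group-label shuffles (add-one-corrected p),
   plus Welch and one-sample t-tests and Bonferroni adjustment.

## Worked example

```r
library(netbursts)
cfg <- synth_config(duration_s = 300, fs = 1000,
                    regions = c("cortex", "striatum"),
                    cooccur_prob = 0.6, lag_ms = 20, seed = 7)
sim <- generate_recording(cfg)
fs  <- sim$recording$fs

lfp <- bandpass(get_channel(sim$recording, "cortex"), fs, 4, 100)
fit <- fit_rms_threshold(windowed_rms(lfp, fs))
fit
#> <gaussian_fit> mu = 14.54 uV, sigma = 2.19 uV, threshold = 21.12 uV
events <- apply_rejection_filters(detect_bursts(lfp, fs, fit,
                                                region = "cortex"))$retained
nrow(events)
#> [1] 28

baseline <- baseline_psd(lfp, fs, events)
feats <- burst_feature_matrix(events, lfp, fs,
           sim$truth$spikes$time_s[sim$truth$spikes$region == "cortex"],
           baseline)
cl  <- fuzzy_cmeans(normalize_and_embed(feats)$scores, 2, seed = 1)
cl
#> <fuzzy_clustering> k = 2, m = 2, FPC = 0.875, 28 events
table(assign_labels(cl, feats)$labels)
#> NGB  SB
#>   6  22

lfp2 <- bandpass(get_channel(sim$recording, "striatum"), fs, 4, 100)
ev2  <- apply_rejection_filters(detect_bursts(lfp2, fs,
          fit_rms_threshold(windowed_rms(lfp2, fs)), region = "striatum"))$retained
pairs <- find_cooccurring(events, ev2)
ps <- pair_segments(pairs[1, ], events, ev2, lfp, lfp2, fs)
cross_spectral_coherence(ps$seg_a, ps$seg_b, fs)
#> <coherence_result:csc> mean 0.610 over 4-40 Hz (9 segment(s))
prewhitened_xcorr_lag(ps$seg_a, ps$seg_b, fs, band = c(4, 16),
                      regions = c("cortex", "striatum"))
#> <lag_result> cortex-striatum 4-16 Hz: lag -20.0 ms (r = 0.697)
```

The fitted threshold sits 3σ above the quiet-mode RMS; 28 events survive
the quality filters and split into 22 SB and 6 NGB with a crisp partition
(FPC 0.875). The generator imposed a 20 ms cortex→striatum onset delay on
co-occurring events, and the pre-whitened cross-correlation reports
−20 ms — negative meaning cortex leads under the cortex–striatum sign
convention — with coherence well above typical independent-pair levels.

A full run (`simulate → detect → classify → spectra → interact → stats`)
is a single call, `run_pipeline(config, out = "results", seed = 1)`, or via
the bundled CLI: `Rscript inst/cli/netbursts.R run-all --config cfg.yaml
--out results --seed 1`.

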