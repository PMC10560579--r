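---
title: "Methods: burst detection, classification and cross-regional inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst detection, classification and cross-regional inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`netbursts`, the assumptions behind them, the parameters that matter, and
the design choices made where the methodology left the design genuinely
open. It is the package's reference for *why* the code does what it does;
the README shows *how* to run it.

## The signal model

Early postnatal LFP in cortex, striatum and thalamus is discontinuous:
oscillatory bursts of a few hundred microvolts ride on a quieter 1/f-like
background. The package models two event classes. A **spindle burst (SB)**
is a narrowband theta–alpha oscillation (default carrier 8 Hz, within the
4–16 Hz band) lasting on the order of a second. A **nested gamma spindle
burst (NGB)** is longer and larger and adds a beta–low-gamma component
(default 25 Hz, within 16–40 Hz) whose amplitude is modulated by the phase
of the spindle component — gamma nested in the spindle cycle. These
definitions drive both the synthetic generator and the classifier's
cluster-identity rule (the cluster with more relative 16–40 Hz power is
NGB).

## Burst detection

Detection works on the 4–100 Hz band-passed LFP (third-order Butterworth,
applied forward–backward). Zero-phase filtering is deliberate: causal
filtering would add a group delay that biases every downstream lag
estimate. The cost is a doubled effective order, which is immaterial here.

RMS values over a fixed grid of non-overlapping 200 ms windows (aligned to
the recording start; a sliding grid would blur onsets) form a histogram
that is mostly the quiet-background mode plus a long right tail from
bursts. A Gaussian is least-squares fitted to this histogram
(Levenberg–Marquardt via `minpack.lm`); the detection threshold is
`mu + 3*sigma`. Binning uses the Freedman–Diaconis width with a floor of
50 bins; the choice is recorded in the fit object. Two safeguards:

* the Gaussian mean is bounded above by 50 µV during fitting — in
  burst-dense recordings an unconstrained fit migrates toward the burst
  mode and then only burst peaks cross threshold; the `capped` flag records
  when the unconstrained mean exceeded the bound;
* if the optimizer fails, the fit falls back to median/MAD estimates with
  a warning and `converged = FALSE`.

Consecutive supra-threshold windows merge into one event; a single
sub-threshold window splits events (no gap bridging). Event durations are
computed as window counts times 0.2 s so boundary comparisons are exact.

**Rejection filters.** Retained events must last 0.2–20 s, contain at
least five oscillation peaks above their mean RMS, and have mean RMS at or
below 1000 µV (anything larger is treated as a movement artifact). The
peak count deserves a note, because its purpose is to exclude amplitude
increases *without* sustained oscillation. Counting local maxima of the
rectified signal exceeding the mean RMS does not achieve that: broadband
4–100 Hz noise carries five or more rectified maxima in a single 200 ms
window essentially always, so that reading passes noise transients nearly
unchanged. The default therefore counts **cycles**: troughs deeper than
the negative of the event's mean RMS whose topographic prominence exceeds
half the event RMS — the same trough definition the inter-trough-interval
feature uses, so the package has one coherent notion of an oscillation
cycle. The rectified-maximum variant remains available as
`peak_mode = "abs"`.

The envelope detector (analytic-signal magnitude thresholded at a
per-recording percentile) is intentionally parameterized rather than
fixed: the right percentile depends on the fraction of time occupied by
bursts. It exists to cross-validate the RMS detector via
`overlap_fraction()`, not to replace it.

## Features, embedding, classification

Nine features per retained event: duration; negative peak (minimum of the
4–100 Hz signal); maximum 200 ms-chunk RMS; flatness (min/max chunk RMS);
maximum absolute slope after resampling the event to 500 S/s (at the raw
rate consecutive-sample differences are dominated by noise); mean
inter-trough interval (ITI) over troughs with prominence above half the
event RMS; relative 4–16 Hz and 16–40 Hz power as fractions of the
baseline-normalized 1–50 Hz spectrum; and spike rate. Degenerate case:
an event with fewer than two qualifying troughs gets ITI equal to its
duration and a flag, keeping the feature matrix rectangular instead of
dropping the event.

Features are z-scored (min–max normalization available) and embedded with
PCA; the first three components feed fuzzy c-means. PCA signs follow a
fixed convention (the largest-magnitude loading of each component is made
positive) so reruns are bit-identical. Constant features are dropped with
a warning rather than poisoning the scaling.

Fuzzy c-means uses fuzzifier `m = 2` — the conventional default, adopted
because the methodology does not pin it — with 10 seeded restarts and the
best objective kept; c-means is initialization-sensitive and restarts make
the labels stable. Convergence is `e1071::cmeans`'s default criterion with
up to 300 iterations. The cluster count is chosen by the fuzzy partition
coefficient (mean squared membership; 1 crisp, 1/k maximally fuzzy),
excluding the trivial k = 1. A monotonically decreasing FPC curve that
never rises above 0.75 triggers a single-cloud warning, since the argmax
at the smallest k then carries no evidence of structure. Events whose
maximum membership does not exceed 0.6 — strictly, so 0.6 itself is
unclassified — are labeled UC. Cluster identity: higher
membership-weighted mean relative beta–low-gamma power means NGB; an exact
tie falls back to mean duration (NGB are longer); a tie on both is refused
with an error asking for a manual override rather than guessed.

## Spectra

PSDs are multitaper estimates: 1 s windows advanced by 0.1 s,
half-bandwidth NW = 3, the first five Slepian sequences, eigenspectra
averaged with unit weights (Thomson adaptive weighting available by
option, but unit weights are the default since the methodology names only
NW and K). The Slepian tapers are computed from the classical symmetric
tridiagonal eigenproblem — accurate to ~1e-10 against standard
implementations — and cached per (length, NW, K). Signals sampled above
1 kS/s are anti-alias-filtered and decimated to at most 1 kS/s before
spectral estimation; all analysis bands live below 50 Hz, so this loses
nothing and keeps the taper eigenproblem small. Segments shorter than 1 s
use a single full-length window (warned); shorter than 0.2 s is an error.

The baseline PSD is the window-count-weighted mean over all non-bursting
gaps longer than 1 s. Every event spectrum is divided pointwise by the
baseline (`P/P0`); baseline bins below 1e-12 µV²/Hz are floored before
division and reported. Band fractions integrate the normalized spectrum
(trapezoidal, with edge interpolation) over 4–16 or 16–40 Hz and divide by
the 1–50 Hz integral.

## Cross-regional interactions

Bursts from two regions co-occur when their onsets differ by strictly less
than 0.5 s; matching is greedy one-to-one by smallest onset difference
(earlier event wins ties), so no event is counted twice. The analysis span
of a pair is the intersection of the two event spans; below 0.5 s, a
single 0.5 s window starting at the later onset is used and flagged.

Welch estimates use 0.5 s Hann windows, zero overlap, per-segment linear
detrend. Cross-spectral coherence is the magnitude-squared coherence;
imaginary coherence is `|Im(Sxy/sqrt(Sxx*Syy))|`, insensitive to zero-lag
(volume-conducted) coupling. The summary statistic is the mean over
4–40 Hz — the union of the two analysis bands, fixed here because the
averaging range was otherwise unspecified. Pairs with mean coherence above
0.8 are rejected as likely movement artifacts.

Significance comes from re-pairing events at random 1000 times
(derangements, so no event keeps its true partner; with too few pairs the
code warns and samples with replacement) and taking the 95th percentile of
the shuffled mean coherences. The implementation precomputes each
segment's windowed FFTs once and assembles the full pair-by-pair coherence
matrix, so shuffles are indexing operations. Two honest properties of this
null are worth knowing: with a single 0.5 s window the Welch coherence of
any pair is identically 1 (flagged `single_window`), and with few pairs
the interpolated 95th percentile of permutation means is slightly
anti-conservative — the package's calibration tests measure the resulting
false-positive rate directly rather than assuming 5 %.

Spike-field coherence bins spikes at 2 ms, band-passes the LFP to 4–80 Hz
and resamples it to the same 500 S/s grid, and takes the absolute real
part of the normalized cross-spectrum; the per-bin null is the 95th
percentile over 1000 uniform relocations of the spike times. Fewer than
10 spikes yields no significance call.

**Lag inference.** Both signals are band-passed to 4–16 Hz (SB) or
16–40 Hz (NGB), then pre-whitened: an AR(p) model (p by AIC over 1–10,
Burg) is fitted to each signal independently and the normalized
cross-correlation computed on the residuals. Pre-whitening is what makes
narrowband lag estimation work at all — without it the cross-correlation
of band-limited signals oscillates at the carrier period and the ±50 ms
argmax is ambiguous; whitened residuals give a single sharp peak. A
`reference` mode (both signals filtered by the first signal's model) is
available; independent fits are the default. If the AR fit fails the code
falls back to first differencing with a flag. Sign convention, stated on
every result object: a positive lag means the second region of the pair
leads; with the canonical pair orders (cortex, striatum),
(thalamus, striatum), (cortex, thalamus) this reproduces the standard
developmental conventions (e.g. positive = striatum leading cortex).
Lags under 20 ms (strictly) are flagged putative monosynaptic. Spike-train
lags smooth both trains with a 2 ms-SD Gaussian on a 1 ms grid, search
±10 ms, and use the opposite, explicitly documented convention (positive =
train B follows train A); a one-sample t-test across pairs tests for a
consistent leader.

## Permutation statistics

The multivariate F statistic is the ratio of between- to within-group sums
of squared Euclidean distances with the degrees-of-freedom normalizations
`K − 1` and `N − K`; on one-dimensional data it reduces exactly to the
classical one-way ANOVA F (verified to 1e-10 in tests). Group labels are
shuffled with group sizes fixed; the p-value uses the add-one correction
`(1 + #{F_perm ≥ F_obs})/(1 + n_perm)`, so it is bounded below by
`1/(n_perm + 1)` and the test is valid at finite permutation counts.
Because the statistic is distance-based it is scale-sensitive; features
are z-scored on the pooled data by default (making the test invariant to
per-feature rescaling), with `normalize = FALSE` for raw units. The
permutation loop computes only group-A column sums per shuffle — the total
sum of squares is permutation-invariant, so F is monotone in the raw
between-group term — which keeps 10,000 shuffles at interactive speed.

## The synthetic-data generator

The generator exists so that every stage can be tested against ground
truth; no public recordings of this preparation exist. It emulates:
1/f^α Gaussian background noise (α = 1, RMS 30 µV), synthesized in the
frequency domain; SB events (default 4/min, lognormal durations with mean
1.3 s) as stochastic narrowband carriers — a cosine whose phase performs a
Brownian walk, giving a ~1.5 Hz Lorentzian linewidth around the 8 Hz
carrier — under an envelope with 0.25 s Hann-shaped rise/fall ramps and a
sustained plateau; NGB events (2/min, mean 4 s, twice the SB amplitude)
adding a 25 Hz component gated by the spindle phase; cross-regional
co-occurrence in which each reference-region event propagates to other
regions with probability 0.5, delayed by a configurable signed lag
(default 20 ms) and mixed as `g·shared + sqrt(1−g²)·independent`
(g = 0.8), giving band-limited coherence with the imposed delay; and
spike trains as background Poisson (1 Hz) plus burst-gated spiking
(8× rate, phase-coupling depth 0.6) with a biphasic ~1 ms template MUA
channel. Event placement is Poisson thinned to forbid same-region overlap,
since overlapping truth events would make recall ill-defined for a
detector that merges contiguous supra-threshold windows.

Two generator choices are worth flagging. The stochastic carrier (rather
than a pure tone) is what makes lag recovery testable: pure tones have
periodic cross-correlations with ambiguous peaks. The plateau envelope
(rather than a full Hann bell) keeps an event near its nominal amplitude
across its nominal span, so truth intervals mean what they say; a full
bell would leave edge cycles far below threshold and blur the
correspondence between truth spans and anything a detector could find.

What the generator does **not** emulate: biophysical burst generation,
age-dependent parameter drift, electrode drift and movement artifacts,
volume conduction between regions, non-Poisson spike statistics, and the
real anatomy of more than one channel per region. Passing recovery tests
on this generator therefore demonstrates the pipeline's correctness and
calibration on signals with the designed statistical structure — not
performance guarantees on any particular real recording.

Where distributions were unconstrained (exact duration and amplitude
laws), the defaults above are explicit stand-ins chosen once to be
realistic for this preparation, not claims about real data.

## Numerical conventions and problem sizes

Times are seconds, 0-based, half-open `[onset, offset)`; amplitudes µV.
Seeds control every stochastic step; derived child seeds stay below 2^31.
Channel selection among candidates minimizes the MAD of the 50–100 Hz
residual — a deterministic stand-in for "lowest noise by visual
inspection" — and can be overridden in the pipeline config.

The test suite exercises the pipeline at desk scale chosen by the package:
10-minute single-region recordings at 1 kS/s for detection and
classification recovery; 500 replicate experiments of 40 independent
2 s pairs (200 shuffles each) for null calibration; five imposed lags ×
two bands on 5-minute two-region recordings for lag recovery; and 500
null replicates of 50 × 9 feature matrices (1000 shuffles) for the
permutation test's error rates. Spectral work in tests runs at
250–1000 S/s, which Nyquist-covers the 1–50 Hz analysis range several
times over.

## Known limitations

* The Welch coherence of a single-window pair is degenerate (≡ 1); such
  pairs are flagged, and their mean coherence should not be interpreted.
* The shuffle-null threshold is mildly anti-conservative at small pair
  counts (measured, not assumed — see the calibration tests); results
  from recordings with only a handful of co-occurring pairs deserve
  caution.
* The RMS-histogram Gaussian fit assumes a dominant quiet mode; recordings
  that are bursting most of the time rely on the 50 µV mean cap, which is
  a heuristic.
* AR pre-whitening assumes approximate within-event stationarity; strongly
  amplitude-modulated events shorten the usable residual correlation and
  widen lag error.
* The fuzzifier (m = 2), UC threshold semantics at exactly 0.6, and the
  4–40 Hz coherence-averaging band are fixed conventions where the
  methodology was silent; all are settable.
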