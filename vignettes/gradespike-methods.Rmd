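---
title: "Methods: graded-amplitude Ca2+ spike and dual-peak EAP analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graded-amplitude Ca2+ spike and dual-peak EAP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradespike)
```

## The problem

Cerebrospinal-fluid-contacting neurons (CSFcNs) fire spontaneous Ca2+
spikes whose amplitude is *graded*: a small mode carried by
low-voltage-activated T-type channels and a large mode recruited through
high-voltage-activated (HVA) Ca2+ channels, visible both in two-photon
GCaMP6f imaging and as a second depolarizing peak in cell-attached
extracellular action potentials (EAPs). `gradespike` implements the full
analysis chain for this kind of data — ΔF/F normalisation, derivative
thresholded spike detection, EAP integration and secondary-peak
quantification, multimodality testing, paired-channel regression — plus a
ground-truth synthetic-data generator so that every stage can be verified
by recovery benchmarks rather than by eye.

## Ca2+ spike detection

Raw fluorescence is normalised as ΔF/F = (F − F0)/F0 with F0 the 15th
percentile of the whole recording (linear interpolation between order
statistics). We use a single per-recording baseline; for drug experiments
this means pre- and post-epochs rendered separately each get their own
baseline.

Spikes are detected on a conditioned derivative: Savitzky-Golay smoothing
(order 3, 300 ms) → first difference (left-aligned, first sample zero) →
5-point running median → Savitzky-Golay (order 3, 166 ms). Window lengths
in seconds are converted to the nearest odd sample count ≥ order + 2, so
30 Hz and 120 Hz recordings run through the same configuration. The
detection threshold is `threshold_k` (default 5) times the median absolute
deviation of the conditioned derivative about its median — the *unscaled*
MAD, ≈ 3.37 σ for Gaussian noise. Because "median absolute difference" is
ambiguous, a second mode (`mad_mode = "difference"`, median of absolute
successive differences) is provided; the deviation form is the default.
Events are local maxima strictly above threshold separated by at least
`min_separation` samples (default 2; ties keep the earlier sample). The
threshold is floored at 1.5 % of the positive derivative range: on
(near-)noiseless traces the MAD collapses below the smoothing filter's
ripple (< 1 % of range), and without the floor ripple maxima would count
as events. The floor does not bind at any realistic noise level.

Each spike reports two times: the derivative-peak sample (its `time`) and
the last sub-threshold sample before it (`onset_time`). Amplitude is the
peak ΔF/F in a 333 ms window centred on the spike time minus the mean
ΔF/F over the 100 ms immediately preceding that window; when the next
spike begins inside the window, the window is truncated at that onset so
summated events are not double counted. The window is *centred* on the
spike (the alternative — starting at it — is not what the amplitude
arrows of spike-triggered averages suggest). SNR is amplitude over the SD
of the 180 ms before the spike onset; measuring before the onset (not the
derivative peak) matters, because the derivative peak sits 2–4 frames into
the rising transient and would otherwise inflate the baseline SD.

## EAP analysis

Current traces are band-pass filtered 6–1500 Hz with a 2nd-order
Butterworth applied forward-backward (zero phase, 4th-order magnitude).
Edges are reflection-padded by one settling length (one period of the low
cutoff) and the mean is removed first, since the band-pass has zero DC
gain and subtracting it avoids a slow settling transient. Traces are
stored depolarizing-positive.

EAPs are local maxima above threshold. The automatic threshold is
5 × MAD of the band-passed trace (floored like the Ca2+ detector); the
scenario runners instead fix a per-cell threshold at half the template's
primary amplitude, mirroring how thresholds are set per cell in real
recordings where the noise floor is far below the primary peak.

The running integral (∫EAP) of an event subtracts the mean of the 1 ms
preceding a −2/+15 ms event window and integrates by the cumulative
trapezoid; its peak is proportional to the peak of the underlying
intracellular action potential and is treated as a relative quantity
only. The window bounds are package choices (the waveforms, not the
bounds, are what the literature shows) and are configurable.

The secondary depolarizing peak is quantified on the peak-aligned mean
waveform: differentiate, smooth (Savitzky-Golay, 0.5 ms), and take the
inflection points of the differential as the zero-crossings of its second
derivative. Noise makes raw zero-crossings useless — the flat baseline
crosses zero constantly — so a crossing only counts when it separates two
opposite-signed curvature lobes that each reach 5 % of the maximum
curvature magnitude (`inflection_min_frac`). The secondary amplitude is
the largest *local maximum* after the third inflection point (the end of
the initial repolarisation); requiring a genuine local maximum means a
single-peak EAP — whose post-inflection tail decays monotonically — is
flagged `no_secondary_lobe` rather than assigned its tail value. On
noise-free templates this measurement recovers the programmed secondary
fraction to better than 0.5 % absolute over scales 0–1.5.

## The synthetic generator

The generator is phenomenological — no conductance models — and exists to
provide ground truth under the study's own conditions:

* **Spike trains** are homogeneous Poisson (default 0.148 Hz, the
  population median spontaneous rate), so ISI CV → 1.
* **Amplitudes** are a two-class log-normal mixture (defaults: small
  median 0.3, large median 1.5 ΔF/F, sdlog 0.25, p(large) = 0.4). The
  class medians are far enough apart that per-cell samples fail a
  normality screen, as most real cells do.
* **Ca2+ transients** are unit-peak double exponentials
  (rise 0.05 s, decay 0.4 s — literature-typical GCaMP6f; the recordings
  this emulates report no kernel, so these defaults cannot be validated
  against them and are fully configurable), sampled at 60 Hz (mid-range
  of 30–120 Hz) with additive white Gaussian noise, default
  sd 0.02 ΔF/F. Transients add linearly.
* **EAP events** are three Gaussian lobes (primary +, repolarizing −,
  secondary +). Widths are FWHM; defaults: primary 25 pA / 1 ms at t = 0,
  repolarizing 8 pA / 0.5 ms at 1.5 ms, secondary at 3 ms / 2 ms wide
  with per-event amplitude `scale × primary`. This geometry was chosen so
  that (a) the third inflection of the differential lands at the end of
  the initial repolarisation and (b) the ∫EAP peak increases strictly
  with the secondary scale across the realistic range — both verified
  numerically.
* **Secondary fractions**: the published median of 23 % (quartiles
  11–37 %) is an *across-cell* statistic, so each cell draws a
  characteristic fraction from a log-normal with median 0.23 whose
  interquartile width matches 0.26 (the quartiles are not log-symmetric,
  so the width — not both quartiles — is matched; sdlog ≈ 0.8). Within a
  cell, per-event scales are log-normal around that fraction with the
  mean preserved (sdlog 0.6), so the cell's mean waveform recovers its
  fraction.
* **Paired recordings** drive both channels from one event list; the Ca2+
  amplitude is `coupling_slope ×` (noise-free ∫EAP peak) plus Gaussian
  coupling noise, so every EAP has a Ca2+ spike and vice versa and the
  expected regression R² is the signal-variance fraction.
* **Conditions**: TTx is the identity (these spikes are Na+-independent);
  Cd2+ reassigns large-class events small-class amplitudes and zeroes
  secondary scales; ML218 thins events binomially (survival 0.05);
  `electrode` superposes an independent Poisson train so the rate triples
  while existing events are preserved (this transform, unlike the drug
  transforms, must create events); ACh/ATP build evoked trains inside
  declared stimulus windows with large-only / small-only amplitudes.

All randomness flows from one explicit seed through a deterministic
sub-seed derivation; the caller's RNG state is saved and restored, and
identical configuration plus seed gives bit-identical output.

## Statistics

The multimodality instrument is the classical Jarque-Bera statistic,
JB = (n/6)(S² + (K − 3)²/4) with biased (population) moment estimators.
Its null distribution converges very slowly to χ²(2), so critical values
at each sample size are the empirical 0.95 quantiles of 10⁴–10⁵
simulated normal samples, cached per (n, α, replicates, seed). A cell is
flagged multimodal when its amplitude JB exceeds the critical value at
its n; under the null this fires ≈ 5 % of the time, which is what the
calibration check measures.

Rates are count/duration; ISI CV uses the sample SD (n − 1) and is
undefined below 3 events. Condition comparisons use Wilcoxon signed-rank
(paired cells), Mann-Whitney (unpaired), or a two-sample
Kolmogorov-Smirnov test on pooled amplitudes normalised by each cell's
control mean. P values are two-sided with no multiple-testing correction.
The activity index is the sum of detected spike amplitudes divided by
recording duration (matching its ΔF/F s⁻¹ unit); because that quantity's
definition is not standardised, a second mode (mean positive conditioned
derivative) is provided, and neither is asserted to be canonical.

## Event matching and benchmarks

Ca2+ spikes and EAPs (or ground-truth events) are matched greedily,
nearest-neighbour, within a tolerance (default one imaging frame for
paired channels, ±3 frames for recovery scoring). A constant latency
between channels — the kernel rise delays the derivative peak by 2–4
frames — is first estimated as the median time difference of a coarse
match and removed, so the tolerance bounds jitter rather than a fixed
offset. Threshold-crossing onsets were rejected as the matching currency
because their latency depends on spike amplitude.

Benchmark and acceptance problem sizes are deliberately modest — single
cells of 300–600 s, 6–12 cell cohorts, 10⁴ null replicates per sample
size — chosen as the smallest sizes at which the Monte-Carlo tolerances
(binomial or 3σ bands) are meaningful.

## What passing tests do and do not show

The generator's noise is white and Gaussian; real two-photon noise is
neither (shot noise, slow drift, neuropil contamination, motion), and
real EAP recordings add line noise and electrode drift. Passing recovery
benchmarks therefore demonstrates the correctness of the chain under the
declared forward model, not performance on arbitrary recordings. Two
consequences are worth stating plainly:

* At 5 × unscaled MAD (≈ 3.37 σ) the detector's false-positive rate on
  white noise is ≈ 2 × 10⁻⁴ per sample (~3–4 spurious events per 300 s
  trace at 60 Hz) — within the < 10⁻³/sample design bound, and harmless
  when real events are plentiful. But in a near-silent epoch (e.g. after
  T-type channel block with 5 % event survival) this floor dominates the
  measured rate: the pipeline reports a ~86–89 % rate reduction where the
  event thinning is truly 95 %. Real recordings with temporally
  correlated noise would have fewer such maxima; under the white-noise
  model the shortfall is structural, not a bug.
* Events closer than the smoothing timescale (~0.2 s) merge into one
  derivative lobe and cost one detection; at 0.148 Hz this bounds
  sensitivity near 0.97 from above.

Other known limitations: the Ca2+ kernel defaults are not validated
against the emulated recordings (none are reported); ∫EAP is relative
(the proportionality constant to membrane potential is unknowable from
extracellular data alone); and the strict monotonicity of the ∫EAP peak
in the secondary scale holds above a small threshold set by the initial
repolarisation charge (< 0.08 with defaults) — below it the integral
peak is governed by the primary lobe alone.
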