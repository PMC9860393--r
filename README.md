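# gradespike

Analysis pipeline for neurons that fire **graded-amplitude Ca²⁺ spikes**
— most prominently cerebrospinal-fluid-contacting neurons (CSFcNs), which
spike through voltage-activated Ca²⁺ channels instead of Na⁺ channels. A
small spike mode is carried by low-voltage-activated T-type channels; a
large mode is recruited through high-voltage-activated (HVA) channels,
which also appear as a **second depolarizing peak** in the cell-attached
extracellular action potential (EAP). The package is aimed at
electrophysiologists and imaging labs who need this analysis chain as
tested, reusable code.

What it implements:

* **Preprocessing** — ΔF/F normalisation, (F − F₀)/F₀ with F₀ the 15th
  percentile of the raw trace; zero-phase 6–1500 Hz band-pass for current
  recordings.
* **Ca²⁺ spike detection** on the conditioned derivative of ΔF/F
  (Savitzky–Golay 300 ms → first difference → 5-point median →
  Savitzky–Golay 166 ms), thresholded at 5× the median absolute
  deviation; per-spike amplitude (333 ms peak window minus the preceding
  100 ms mean, truncated at the next spike's onset) and SNR (amplitude /
  SD of the 180 ms before onset).
* **EAP analysis** — detection, peak-aligned mean ± SD waveform, running
  integral ∫EAP (proportional to the intracellular action potential),
  and the secondary depolarizing amplitude, read as the maximum after the
  **third inflection point of the EAP's differential**.
* **Statistics** — firing rate and ISI CV (= 1 for a Poisson process),
  the Jarque–Bera statistic JB = (n/6)(S² + (K−3)²/4) against
  **Monte-Carlo critical values** to flag multimodal amplitude
  distributions, per-cell mean-normalised amplitude pooling, OLS
  regression of Ca²⁺ amplitude on ∫EAP, Wilcoxon / Mann–Whitney / KS
  condition comparisons, and an activity index (ΔF/F s⁻¹).
* **A ground-truth synthetic generator** — Poisson trains, two-class
  log-normal amplitude mixtures, GCaMP6f-like transients, three-lobe EAP
  templates with per-event secondary scales, paired recordings with
  linear Ca²⁺↔∫EAP coupling, and condition transforms (TTx, Cd²⁺, ML218,
  electrode perturbation, ACh/ATP evoked trials) — so every stage is
  verified by recovery benchmarks with known event times and amplitudes.

## Worked example

```r
library(gradespike)

# simulate one cell's spontaneous recording (10 min at 60 Hz)
sim <- simulate_spontaneous_cell(rate = 0.148, duration = 600, seed = 42)
events <- analyze_ca_trace(dff(sim$raw))
cell_result("cell_01", events, duration = 600, seed = 43)

# paired Ca2+/EAP recording: regression of spike amplitude on EAP integral
pr <- run_paired(duration = 300, seed = 11)
```

which prints (via the summary fields):

```
rate 0.155 Hz | ISI CV 0.81 | 93 spikes | JB 15.5 (crit 5.4) -> multimodal: TRUE | mean SNR 41.3
matched 111 events | R^2 = 0.45 | slope 20.4 dFF per pA s
secondary peak: 5.3 pA = 22% of primary
```

Read: this simulated cell fires at 0.155 Hz (the generator's Poisson rate
is 0.148 Hz); its spike-amplitude distribution is flagged multimodal
because the Jarque–Bera statistic (15.5) exceeds the simulated 5 %
critical value at this sample size (5.4) — the expected signature of the
small/large spike mixture. In the paired run, Ca²⁺ spike amplitude
regresses on the EAP integral with R² = 0.45 (coupling plus measurement
noise), and the mean EAP waveform carries a secondary depolarizing peak
at 22 % of the primary — close to this cell's programmed fraction of
23 %.

The scenario runners `run_spontaneous()`, `run_paired()`,
`run_pharmacology()` and `run_benchmark()` orchestrate multi-cell
versions of these analyses with per-cell tables, population summaries and
condition tests; `write_traces()` / `read_traces()` exchange recordings
as delimited text with a JSON sidecar.

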