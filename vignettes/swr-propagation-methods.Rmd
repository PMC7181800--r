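---
title: "Methods: detecting and tracing sharp-wave ripples from CA1 to retrosplenial cortex"
author: "swrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and tracing sharp-wave ripples from CA1 to retrosplenial cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swrpipe)
```

`swrpipe` implements the analysis chain used to study how hippocampal
sharp-wave ripples (SPW-Rs) — transient 140–200 Hz oscillations riding on a
sharp-wave deflection in CA1 — propagate to the granular retrosplenial
cortex (gRSC), where they appear as superficial-layer ripples coupled to
large negative LFP waves that reverse polarity in depth. This vignette
documents the models behind each stage, the tunable parameters, and the
numerical and design choices that were genuinely open.

## The synthetic session generator

Raw recordings of this kind are rarely shareable at desk scale, so the
package ships a deterministic generator (`synth_config()`,
`generate_session()`) whose defaults encode the phenomenology the analyses
target:

* **CA1 channel.** Pink (1/f) background noise of unit SD carrying
  Hann-enveloped ripple bursts (default 170 Hz carrier, 0.68 events/s,
  peak amplitude `ripple_snr` = 8 noise SDs) superimposed on a negative
  Gaussian sharp wave (SD 15 ms). `ripple_duration_ms` (default 26) is
  defined as the FWHM of the Hann envelope, so the detector's
  over-threshold span and cycle counts land near the nominal values
  (about 5 cycles at 170 Hz).
* **gRSC probe.** Eight depth channels. A fraction
  (`propagation_prob` = 0.35) of CA1 ripples arrive after
  `propagation_delay_ms` = 5 ms as a superficial negative wave whose
  polarity reverses on the deep channels, plus a ripple burst confined to
  the superficial half of the probe.
* **Spike trains.** Inhomogeneous Poisson units (log-normal baseline
  rates around 2.5 Hz for pyramidal cells and 14 Hz for interneurons,
  with a 2.5 ms refractory period imposed, as spike sorting would).
  During ripples a unit's rate is multiplied by `ripple_gain` and its
  in-burst spikes are drawn with von Mises phases around a unit-specific
  preferred phase (concentration `phase_lock_kappa`; phase 0 = band
  peak), so the inter-trial phase clustering of a unit converges to the
  analytic resultant I1(k)/I0(k).
* **Brain states.** The session cycles through synchronized,
  desynchronized/low-EMG and desynchronized/high-EMG epochs (exponential
  dwell, mean 40 s, floor 5 s). In the synchronized state all rates are
  gated into quasi-periodic activity packets (default 4/s, within the
  3–10 Hz packet band) separated by near-silence; packet spacing is
  drawn as (0.9–1.4)/rate so silent troughs outlast the 30 ms MUA
  smoothing kernel — with purely exponential spacing, close packet pairs
  would fuse after smoothing and no detector could resolve them. A
  common 300–600 Hz contaminant, strong only in high-EMG epochs, is
  added to every channel.
* **Ripple types.** `plant_ripple_types()` assigns units round-robin to
  `n_ripple_types` templates; a ripple of type *t* multiplies the ripple
  gain of the units in template *t* by `1 + type_separation`, over the
  100 ms window used downstream for rate vectors. `grsc_type_coupling`
  does the same for gRSC units over 200 ms, creating (or, at 0,
  withholding) a downstream correlate of ripple identity.

All randomness flows from one seed through per-component sub-streams, so
the spike trains are bit-identical whether or not the LFP is generated
(`generate_session(cfg, lfp = FALSE)` is used for spike-only analyses).

What the generator does **not** emulate: volume conduction beyond
per-channel scaling, theta or slow-oscillation rhythms, electrode drift,
sorting errors, bursty (non-Poisson) discharge, and ripple-frequency
chirps. Tests passing on this generator therefore validate the
*computations* — thresholds, formulas, calibrations — not robustness to
every pathology of real recordings.

## Detection stages

**Ripples.** The LFP is band-passed 100–280 Hz with a 2nd-order
Butterworth applied forward and backward (zero phase; odd-reflect padding
of nine filter lengths keeps the edges stable), rectified, and smoothed
with a Savitzky–Golay filter (11 ms window, order 2 — the window and order
are exposed since the classical recipe leaves them open). Events require
the smoothed envelope above mean + 2 SD and the filtered trace above
mean + 4 SD for at least 20 ms; of two events with peaks closer than
40 ms the smaller is discarded. Means and SDs are taken over the whole
trace in a single pass (the simplest reading of "above the respective
mean"; an iterative re-estimate excluding detected events was considered
and rejected as under-specified). Because thresholds are in SD units,
detection times are invariant to rescaling the trace. Sessions with fewer
than 100 events should be flagged (`min_events_for_session`).

**Negative waves.** Template matching against a negative-going template,
thresholded at 1 RMS of the matched-filter output. Since a manually
curated template cannot be reproduced, `negative_wave_template()` builds a
session-adaptive one: the average of the 50 largest low-passed (< 30 Hz)
negative deflections. The matched peak must itself deflect below zero —
without this, a polarity-inverted wave can trigger on the side lobes that
mean-removal introduces into the template.

**Packets and states.** The MUA population rate (1 ms bins, Gaussian
smoothing SD 30 ms, refused below 16 units) is scanned for local maxima
exceeding the local 10 s average by 60% for at least 25 ms, flanked
within 1 s on both sides by ≥ 25 ms troughs below 20% of the local
average; packets closer than 15 ms merge. A 40 ms minimum-excess variant
exists in the literature of this procedure; 25 ms is the default here and
the parameter is exposed. The state index (SI) is the fraction of nonzero
1 ms count bins in a sliding 0.5 s window; the EMG proxy is the mean
pairwise zero-lag correlation of 300–600 Hz-filtered channels in 0.5 s
windows. Both distributions are cut at the valley of a kernel-smoothed
density between the two largest modes (fixed fallback cutoffs with a
warning when unimodal); synchronized = low SI, and the EMG cut splits the
desynchronized time. Intervals shorter than 2 s are absorbed.

## Spectral statistics

Wavelet analysis uses complex Morlet kernels with the number of cycles
log-interpolated from 3 at the lowest to 12 at the highest analysed
frequency (the classical recipe states only "logarithmically spaced");
kernels are scaled to give unit response to a unit sine. Event-triggered
maps are z-scored per event and frequency against a baseline ending at
least 100 ms before the event. Phase is extracted by the filter–Hilbert
method with the peak = 0 / trough = ±π convention recorded in every
output. ITPC is the resultant length of the phase set; phase preference is
deemed significant at Rayleigh p < 0.05 *and* ITPC > 0.1, evaluated at
the ripple trough time–frequency point. Spike–field coherence is
multitaper (5 Slepian tapers, time–bandwidth 3) over ±100 ms windows
around event peaks.

**Phase–amplitude coupling.** The modulation index is the KL divergence of
the phase-binned (50 bins) mean-amplitude profile from uniform, divided by
log 50, with the 0·log 0 = 0 convention so the single-occupied-bin case is
exactly 1. Defaults follow the standard grid: 39 phase frequencies
(2–40 Hz), 91 amplitude frequencies (50–500 Hz), 200 circularly shifted
surrogates with shifts uniform in [1 s, T − 1 s]; the outermost second on
each side is excluded from the binned estimate because phase and
amplitude series share wavelet edge attenuation there, which would make
the unshifted pairing non-exchangeable with the surrogates. A z-score
(Pz) against the surrogates is reported, but masking uses the empirical
surrogate tail
p = (1 + #{MI_sur ≥ MI}) / (1 + n_sur): the MI null is right-skewed and
the normal tail of Pz was measurably liberal (≈ 8% false positives at a
nominal 5%) in zero-coupling calibration runs.

## Laminar analyses

The inverse CSD uses the delta-source variant: each electrode depth hosts
a planar disk source (default diameter 500 µm) in a homogeneous medium;
the forward matrix F with entries (h/2σ)(√(Δz² + R²) − |Δz|) is inverted
after subtracting the shank-average reference. Sinks are negative. The
matching forward model (`forward_csd_potential()`) makes recovery of
planted sources an exact test. CSD is meant for event-triggered averages
(> 150 events), not single trials; note that oblique probe insertion
violates the vertical-conductivity assumption and the package documents
rather than models this. ICA loadings come from a JADE implementation
(joint diagonalization of fourth-order cumulant matrices after PCA
whitening); the event-locked component is the one whose event-triggered
average carries the most loading-weighted variance, and superficial
vs deep loadings are compared with a two-sided rank-sum test.

## Spike-train statistics

PETHs use events separated by ≥ 500 ms (an event survives only if *both*
neighbours are far enough — the stricter of the two possible readings).
Significance follows a convolution scheme: the per-bin Poisson prediction
is the Gaussian-smoothed (SD 10 ms) PETH with the test window's counts
replaced by the baseline mean before smoothing, so a response cannot
inflate its own prediction; acceptance bands are Bonferroni-corrected to a
global α = 0.01 across test-window bins. Calibration on null Poisson
units runs at or below the nominal rate.

The standardized cross-covariance follows the printed formulas:
CCE = CCH/(bT) − R1·R2, standardized by √(bT/(R1·R2)), with T the total
duration of the restriction interval set and rates measured inside it;
independent trains give values of mean 0 and SD 1. The observation period
T is the restricted duration (not the reference spike count), matching
the formula's symbols.

## Ripple typing and downstream discrimination

Rate vectors count spikes of non-fast-spiking CA1 units in 100 ms after
ripple onset, z-scored per unit across ripples (the normalization was
unspecified; min–max is available as an option). k-means with k = 10 and
squared Euclidean distance, seeded restarts for determinism. The
similarity matrix is the label-sorted Pearson correlation of rows.

Downstream discrimination is an ANCOVA — OLS with label dummies plus the
CA1 population rate as covariate, F-test on the label block — per unit and
10 ms lag bin (covariate counted in the same bin), with "discriminates" =
any post-onset bin at p < 0.01 and a label-shuffle F null available as a
guard. The LFP variant z-scores 80 log-spaced bands (5–300 Hz) within the
±500 ms window per ripple, tests per (band, lag), combines sessions with
Fisher's method (−2Σlog p ~ χ² with 2n d.f.) and masks at p < 0.0004.

t-SNE embeddings (exact O(n²) implementation: perplexity-calibrated
Gaussian affinities, Student-t kernel, momentum + adaptive gains, early
exaggeration, isotropic Gaussian initialization) are computed separately
for the CA1 (100 ms) and gRSC (200 ms) rate vectors. Per-label densities
on a 1 AU grid, smoothed with a 2-D Gaussian of σ = 4 AU and normalized
by label size, are compared against label permutations; bins with
permutation p < 0.01 form the significant regions.

## Problem sizes and tolerances used in validation

The shipped tests and the acceptance script run on sessions of 300–600 s
with the default unit counts (75 units), 10-type sessions with separation
6 for clustering recovery, 500–1000 simulated units for PETH/ANCOVA
calibration, 60–100 seeded runs for PAC masking calibration, and 500–1000
label permutations for the t-SNE test. Statistical calibration checks are
asserted at their nominal levels within binomial confidence bounds of the
simulation sizes; recovery checks use the tolerances natural to each
quantity (one sample or bin for time lags, 1% relative error for filter
gains). Degenerate inputs — constant traces, empty spike trains, flat
templates, rank-deficient channel data, all-identical rate vectors — are
either well-defined (zeros, label collapse) or rejected with informative
errors, as exercised in the test suite.

## Known limitations

* Detection thresholds assume roughly stationary noise; long artifacts
  would inflate the SD baseline (the in-vivo practice of visual
  inspection has no desk-scale equivalent here).
* The CSD delta-source model assumes homogeneous, vertical conductivity.
* The ANCOVA treats spike counts as homoskedastic; calibration shows the
  F-test holds its level at the rates simulated, but very sparse bins
  would benefit from a count model.
* Exact t-SNE is quadratic in the number of ripples; sessions beyond a
  few thousand ripples would need a tree-based approximation.
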