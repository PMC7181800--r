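# swrpipe

Analysis of hippocampal sharp-wave ripple (SPW-R) propagation to the
granular retrosplenial cortex (gRSC) from multichannel extracellular
recordings — for electrophysiologists who need the full in-vivo analysis
chain as tested, reusable R functions rather than one-off scripts.

SPW-Rs are transient 140–200 Hz oscillations of the CA1 local field
potential riding on a sharp-wave deflection. A fraction of them propagate,
with a few milliseconds' delay, to superficial gRSC, where they appear as
local ripples coupled to large negative LFP waves whose polarity reverses
in depth. `swrpipe` covers:

* **Detection** — ripples (100–280 Hz band-pass, envelope > mean + 2 SD
  and filtered trace > mean + 4 SD for ≥ 20 ms, 40 ms peak-merge rule),
  negative waves (matched filter at 1 RMS), population activity packets.
* **Spectral statistics** — complex Morlet spectrograms and baseline
  z-scored event-triggered maps; cross-regional phase coherograms;
  multitaper (5 tapers, TW = 3) spike–field coherence; filter–Hilbert
  phase; ITPC = |n⁻¹ Σ e^{iφ}| with Rayleigh significance (p < 0.05 and
  ITPC > 0.1); phase–amplitude coupling via the KL modulation index
  MI = [log N − H(P)]/log N over 50 phase bins with 200 shift surrogates.
* **Laminar structure** — delta-source inverse CSD (solve F·CSD = φ for a
  cylindrical-disk forward matrix) and JADE ICA voltage loadings.
* **Spike-train statistics** — unit QC (rate ≥ 0.5 Hz, ISI violations
  ≤ 1%), k-means pyramidal/interneuron typing, PETHs with
  convolution-based Poisson significance bands, and the standardized
  cross-covariance CCE·√(bT/(R1·R2)) with CCE = CCH/(bT) − R1·R2.
* **Brain states** — smoothed-MUA packet detection, the state index
  (fraction of nonzero 1 ms bins in 0.5 s windows), an EMG proxy from
  300–600 Hz channel correlations, and bimodal-valley segmentation into
  synchronized / desynchronized(low EMG) / desynchronized(high EMG).
* **Ripple typing** — per-ripple ensemble rate vectors, k-means (k = 10)
  typing, per-unit and per-frequency-band ANCOVA discrimination of ripple
  type (CA1 population rate as covariate, Fisher χ²(2n) combination
  across sessions), and t-SNE density permutation tests.
* **Synthetic sessions** — a deterministic two-region generator with full
  ground truth (ripple times and types, propagation delays, states,
  packets, per-unit preferred phases), so every stage is testable without
  external data.

## Worked example

```r
library(swrpipe)

cfg <- synth_config(duration = 300, seed = 42)   # 5 min, two regions
session <- generate_session(cfg)

ripples <- detect_ripples(session$ca1$samples[1, ], cfg$fs, channel = 1)
ripples[1:3, ]
#>    onset   peak offset amplitude channel
#> 1 1.2752 1.2896 1.3072  5.467264       1
#> 2 2.4912 2.5080 2.5224  5.221045       1
#> 3 3.8568 3.8744 3.8920  5.270203       1
nrow(ripples)
#> [1] 186

match_events(session$truth$ripples$peak, ripples$peak, tol = 0.02)$sensitivity
#> [1] 1

# propagation delay: lag of the gRSC ripple-band power peak per CA1 ripple
sup <- which(session$grsc$channels$region == "gRSC_sup")[1]
env <- sqrt(ripple_band_power(session$grsc$samples[sup, ], cfg$fs))
prop <- session$truth$ripples[session$truth$propagated, ]
peak_power_lags(prop, env, cfg$fs, window = c(-0.01, 0.02))[c("median_ms", "sem_ms")]
#> $median_ms
#> [1] 5.6
#> $sem_ms
#> [1] 0.2661276

# brain states from population activity + EMG proxy
mua <- smoothed_mua(session$spikes, cfg$duration)
states <- segment_states(state_index(mua, step_s = 0.05),
                         emg_from_lfp(session$grsc))
table(states$label)
#> desync_highEMG  desync_lowEMG   synchronized
#>              1              1              2
```

The detector recovers every planted event at the default signal-to-noise
ratio; the recovered propagation lag (median 5.6 ms) sits one LFP sample
above the generator's 5 ms delay; and the session's state sequence is
segmented into the three planted regimes.

`run_pipeline(pipeline_config(...))` chains all stages (detection →
spectral/laminar → units/state → typing) and writes TSV outputs plus a
manifest; `inst/cli/swrpipe.R` is a thin command-line front-end
(`synthgen`, `detect-ripples`, `run-all`).

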