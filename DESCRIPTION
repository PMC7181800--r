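Package: swrpipe
Title: Detection and Cross-Regional Analysis of Hippocampal Sharp-Wave Ripples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing propagation of hippocampal sharp-wave ripples
    (SPW-Rs) to the granular retrosplenial cortex from multichannel
    extracellular recordings: ripple and negative-wave detection, event
    cross-correlograms with jitter confidence bands, Morlet wavelet
    spectrograms and phase coherograms, spike-LFP phase locking (ITPC,
    Rayleigh test), multitaper spike-field coherence, phase-amplitude
    coupling modulation index with shift surrogates, inverse current-source
    density and ICA laminar profiles, peri-event time histograms with
    convolution-based significance, standardized spike-train
    cross-covariance, population activity-packet detection and brain-state
    segmentation, and k-means ripple-type clustering with ANCOVA-based
    downstream discrimination and t-SNE density permutation tests. Includes
    a deterministic synthetic two-region session generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
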