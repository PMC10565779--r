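Package: ephysquant
Title: Quantification of Intrinsic Excitability, Synaptic Plasticity and
    Molecular Ratios in Hippocampal Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for cellular and synaptic neurophysiology:
    passive membrane properties, ramp rheobase and action-potential waveform
    features from whole-cell current-clamp traces (phase-plane threshold,
    amplitude, half-width, maximal rise slope, fast afterhyperpolarization);
    field-potential quantification (fiber volley and fPSP amplitudes, 20-80
    percent rising-phase slopes, input-output curves, paired-pulse ratios,
    frequency-facilitation tuning curves, LTP/de-potentiation/LTD time
    courses, fiber-volley trajectories); relative expression by 2^-ddCq,
    Western-blot densitometry ratios, and threshold-based VGLUT1/MAP2
    fluorescence ratios. A synthetic-data module (adaptive exponential
    integrate-and-fire neuron, Tsodyks-Markram dynamic synapse, field-sweep
    renderer, plasticity time courses, two-channel image synthesizer, qPCR
    tables) provides ground truth so every analysis stage is verifiable
    without recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    minpack.lm,
    stats,
    utils,
    tools,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
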