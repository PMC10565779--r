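# ephysquant

Quantification pipeline for cellular and synaptic neurophysiology of the
hippocampal CA1 region, written for studies that combine whole-cell
current-clamp recordings, extracellular field-potential plasticity
experiments, and supporting molecular read-outs (RT-qPCR, Western blots,
two-channel immunofluorescence). Every analysis stage is paired with a
synthetic-data generator carrying exact ground truth, so the whole pipeline
is testable without any recording hardware or animal tissue.

## What it computes

**Intrinsic excitability** (current-clamp traces, 20 kHz):

- resting membrane potential (RMP) from a pre-stimulus window, with
  liquid-junction correction and a contaminated-baseline guard;
- spike detection as upward dV/dt crossings (default 20 mV/ms, 2 ms
  refractory);
- action-potential threshold from the phase-plane plot: with the smoothed
  derivative g = dV/dt plotted against V along the upstroke, the threshold
  is the voltage at which d(g)/dV is maximal;
- AP waveform features: threshold-to-peak amplitude, half-width at
  half-amplitude with sub-sample interpolation, maximal rise slope, fast
  afterhyperpolarization (fAHP) amplitude and delay;
- ramp analysis (e.g. 0–100 pA in 2 s): spikes per ramp and rheobase, the
  injected current at the first AP's threshold crossing;
- passive properties from subthreshold steps: R_N = dV/dI, tau_m from a
  single-exponential fit, C_m = tau_m / R_N.

**Field-potential plasticity** (stratum radiatum fPSPs):

- per-stimulus fiber-volley (FV) and fPSP amplitudes plus the 20–80%
  rising-phase slope, with artifact blanking and template peeling of
  overlapping responses at short inter-stimulus intervals;
- input–output curves with intensity-for-fraction lookup (30% / 50% of
  maximum for LTP / LTD experiments);
- paired-pulse ratios (ISI 10–500 ms) and 100-pulse frequency-facilitation
  trains with last-10-pulse summaries and tuning curves across 1–100 Hz;
- LTP / de-potentiation / LTD time courses normalized to percent of
  baseline, with window means ± SEM (51–60 min post-HFS, 41–50 min post-DP,
  35–40 min post-LFS) and a baseline-drift gate;
- fiber-volley trajectories under FV isolation, with last-5-min-of-LFS and
  post-LFS window summaries.

**Molecular quantification**:

- relative expression by 2^-ddCq (technical replicates averaged on the Cq
  scale, group-anchored ddCq);
- Western-blot densitometry: background-corrected target / beta-actin
  ratios, replicate-averaged per sample;
- blinded threshold-based VGLUT1/MAP2 ratio: total above-threshold VGLUT1
  intensity normalized to MAP2-positive pixel area.

**Statistics**: unpaired two-tailed Student's t (pooled variance; Welch
behind a flag), one-way ANOVA with Tukey HSD, mean ± SEM summaries and
significance stars, and a manifest-driven `run_pipeline()` that chains
simulation/reading, analysis, group statistics and CSV/JSON output
deterministically.

**Synthetic generators**: an adaptive exponential integrate-and-fire (AdEx)
neuron (forward Euler at 20 kHz, Rcpp), a Tsodyks–Markram
facilitation/depression synapse, a field-sweep renderer (biphasic artifact +
Gaussian FV + difference-of-exponentials fPSP), plasticity time courses,
two-channel dendrite/puncta images, and qPCR Cq tables — all seeded and
bit-reproducible, all emitting exact ground truth.

## Worked example

```r
library(ephysquant)

# a ventral-like pyramidal cell: depolarized rest, high input resistance
cell <- neuron_params(E_L = -73, R = 240, C = 75, V_T = -58)
ramp <- protocol_spec("ramp", i_start = 0, i_end = 100, duration = 2)
tr <- simulate_neuron(cell, ramp, seed = 104)

measure_rmp(tr)
#> [1] -72.99893
analyze_ramp(tr)
#> <ramp_result> 9 spikes, rheobase 58.9 pA, from -73.00 mV

seg <- detect_spikes(tr)$segments[[1]]
ap_features(seg)
#>   threshold amplitude half_width max_rise_slope fahp_amp fahp_delay
#> 1 -48.41816  78.41816 0.06727208       871.3756       NA         NA

# paired-pulse facilitation of a dynamic synapse, rendered and re-measured
syn <- stp_params(U = 0.2, tau_f = 200, tau_d = 500)
amps <- simulate_stp_train(syn, n_pulses = 2, isi_ms = 50)
sw <- synthesize_field_sweeps(amps, field_kinetics(noise_sd = 0),
                              protocol_spec("paired_pulse", isi = 50))
paired_pulse_ratio(sw)
#> [1] 1.329331
```

The RMP is the cell's resting potential in mV; the ramp result counts APs
during the 2 s ramp and converts the first AP's threshold-crossing time to
the rheobase current. The paired-pulse ratio of 1.33 is facilitation: the
second fPSP is 33% larger than the first at a 50 ms interval, matching the
state-model recurrence for these synapse parameters. (The AdEx model
truncates spikes at a cutoff, so its half-width is a grid-level number and
its after-potential keeps hyperpolarizing under the adaptation current,
leaving the fAHP undefined; waveform features are meaningful on recorded or
constructed AP shapes.)

A complete multi-experiment run from a JSON manifest:

```r
manifest <- system.file("extdata", "manifest_demo.json", package = "ephysquant")
run_pipeline(manifest, "out/")   # writes *_cells.csv, *_stats.csv, run_log.json
```

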