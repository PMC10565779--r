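---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephysquant)
```

This vignette documents the models behind `ephysquant`, the estimators it
implements, the numerical choices that matter, and the places where a
convention had to be fixed among several defensible ones.

## Data model and units

All waveform analysis runs in canonical internal units — mV for voltage, pA
for current, ms for waveform features, seconds for epoch times — and readers
convert on ingest (`read_sweeps()` accepts V/mV/uV, nA/pA, s/ms). A `trace`
is a uniformly sampled sweep with sample *k* at `t0 + k*dt` (0-based);
stimulus times always refer to the onset of the stimulus artifact. Files
whose time stamps deviate from uniformity by more than 1% of the sampling
interval are rejected rather than resampled: at that point the file is
either corrupted or was processed elsewhere, and silently regridding it
would hide that. Vendor binary formats are deliberately outside the core; a
user adapter can construct `trace`/`field_sweep` objects from any source.

## The model neuron

The synthetic current-clamp source is the adaptive exponential
integrate-and-fire (AdEx) model,

$$C\,\dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} - w + I(t),
\qquad \tau_w \dot w = a (V - E_L) - w,$$

with $g_L = 1/R$, a spike registered when $V$ reaches the cutoff
`V_peak` (the sample is clipped there), reset to `V_reset`, and
$w \mathrel{+}= b$. Integration is forward Euler at `dt = 0.05` ms (20 kHz,
the acquisition rate the pipeline targets), in compiled code. The
exponential argument is capped at 30 — beyond that the next step is clipped
to `V_peak` anyway, so the cap only prevents floating-point overflow within
a step.

Defaults (`neuron_params()`) emulate a dorsal-like CA1 pyramidal cell:
`E_L = -76` mV, `R = 200` MΩ, `C = 80` pF ($\tau_m = 16$ ms), `V_T = -58`
mV, `Delta_T = 2` mV, `b = 20` pA with `tau_w = 150` ms for
spike-frequency adaptation, `a = 0`. With these values the standard
0–100 pA / 2 s ramp elicits a few adapting spikes with a rheobase in the
80–90 pA range; a depolarized, higher-resistance parameterization
(`E_L = -73`, `R = 240`) fires more and earlier, reproducing the
dorsoventral ordering at the level where it is testable. `a = 0` by default
keeps the subthreshold response a pure RC relaxation, so passive-property
recovery is exact up to integration error; users modelling subthreshold
resonance can set `a > 0`, accepting that the measured `R_N` then reflects
the effective conductance $g_L + a$.

Two facts about this model shape the test design:

- **Quasi-static rheobase.** On a slow ramp the spike appears when the
  current reaches $\approx (V_T - E_L)/R$ (the hard-threshold limit); the
  exponential term advances this by up to $g_L \Delta_T$ and the finite ramp
  speed delays it. The rheobase checks therefore compare the coarse
  integration against a 10× finer-step integration of the same model and
  ask that the hard-threshold limit lie inside that band.
- **No interior phase-plane maximum.** The AdEx upstroke accelerates
  monotonically up to the cutoff, so the phase-plane slope-maximum
  threshold is not a convergent quantity on AdEx spikes (it moves with the
  sampling rate). The threshold operator is therefore validated on a
  constructed AP family (below), and AdEx thresholds are only bounded, not
  pinned.

Observation noise is additive Gaussian on the recorded voltage, not
injected into the dynamics; this keeps the ground truth of spike times and
passive properties exact at any noise level. Every generator takes an
explicit integer seed and is bit-reproducible; no global RNG state leaks
(`with_seed` restores the caller's RNG).

## Spike detection, threshold and waveform features

Detection is the conventional dV/dt criterion: an upward crossing of
20 mV/ms (configurable) with a 2 ms refractory period. The derivative is a
Savitzky–Golay differentiation filter, order 3, 7 samples (0.35 ms at
20 kHz) — raw finite differences at 20 kHz are noise-dominated on real
recordings.

The AP threshold follows the phase-plane definition: plot the smoothed
$dV/dt$ against $V$ along the upstroke (segment start to the $dV/dt$
maximum, trimming the smoother's half-window at the top where the filter
rings), then find the voltage at which the slope of that curve is maximal.
Two numerical details are load-bearing:

- the curve is resampled onto a **uniform voltage grid** (0.1 mV) before
  differencing. On the raw samples the voltage spacing varies with the
  local speed, and tiny denominators in slow regions amplify smoothing
  leakage into spurious slope maxima;
- the resampling uses a cubic spline rather than linear interpolation, so
  the differenced curve does not inherit sample-grid kinks.

A segment whose upstroke has constant slope (e.g. a linear voltage ramp)
has no phase-plane maximum and raises a threshold-undefined error.

Waveform features fix the following conventions, each flagged because the
field uses more than one: **amplitude is threshold-to-peak** (not
baseline-to-peak); **half-width** is the time between the two crossings of
threshold + amplitude/2, linearly interpolated between samples; **maximal
rise slope** is taken from raw sample differences (the smoothed derivative
overshoots at sharp corners); the **fAHP is referenced to threshold**, its
delay measured **from the AP peak**, searched within 20 ms after the peak
(reported delays in CA1 are ~2–3 ms, so 20 ms is safely inclusive), and it
is reported as undefined — not an error — when no interior minimum below
threshold exists in the window. Ramp analysis counts spikes within the ramp
epoch only and maps the first AP's threshold-crossing time linearly to
current; per convention, rheobase values from steeper rescue ramps may be
pooled into rheobase summaries while spike counts come only from standard
ramps. The first AP of the ramp from rest is the canonical segment for
per-cell waveform reporting.

Passive properties come from the current-clamp route: `R_N` is the
steady-state deflection over the step current, $\tau_m$ a single-exponential
fit to the relaxation (Levenberg–Marquardt, with a log-linear fallback if
the fit degenerates), and $C_m = \tau_m / R_N$. The amplifier-style
"membrane test" from voltage-clamp transients is intentionally not
implemented — it is instrument-defined — so capacitance is always the
$\tau/R$ estimate.

## The dynamic synapse and field-sweep rendering

Short-term plasticity follows the Tsodyks–Markram two-variable recurrence
with the update order fixed (conventions differ): at each pulse, read the
response $u_n R_n$; facilitate $u \leftarrow u + U(1-u)$; deplete
$R \leftarrow R - u_n R_n$; then relax $u \to U$ with $\tau_f$ and
$R \to 1$ with $\tau_d$ over the inter-stimulus interval. Responses are
normalized to the first pulse. The test suite re-derives this recurrence
with an independently written scalar-state oracle and checks equality to
1e-12 across a parameter grid.

Rendered field sweeps are a sum of closed-form parts per stimulus: a brief
biphasic artifact (one sine cycle, 0.4 ms), a Gaussian fiber volley of
fixed depth (0.5 mV by default, the magnitude FV-isolation experiments aim
for; optionally scaled per pulse to emulate FV suppression), and a
difference-of-exponentials fPSP whose unit peak is scaled by the pulse's
relative amplitude. All deflections are negative-going, as in stratum
radiatum. The default kinetics place the fPSP peak ~6.6 ms after the
stimulus, so even 100 Hz trains keep the peak inside the inter-stimulus
window; when a parameterization violates that, the renderer records an
overlap warning but still renders.

Measurement blanks the artifact window, takes the FV as local-baseline-to-
trough in a 0.5–2.5 ms window, the fPSP as baseline-to-extremum (clipped at
the next stimulus; a peak pinned to the clipped edge sets a truncation
flag), and the slope as the least-squares line through the 20–80% rising
phase. Two choices matter for accuracy:

- **Template peeling.** At short intervals the fPSP of one stimulus rides
  on the tail of the previous one. Responses are measured in time order and
  each measured fPSP is subtracted (a unit-peak template scaled by the
  measured amplitude) before the next stimulus is measured. The template is
  the analytic kernel when known (synthetic closure), or a sampled template
  from an averaged isolated baseline response for recorded data; the mode
  is config-switchable to raw measurement.
- **Dense resampling of the slope interval.** The 20–80% crossings are
  located by interpolation and the rising phase is spline-resampled onto
  200 points over exactly that interval before fitting. Fitting the raw
  samples instead biases the slope by ~1% because the sample grid truncates
  the interval asymmetrically.

Paired-pulse ratios use amplitudes by default (slope optional); plasticity
time courses use slopes; input–output curves use amplitudes. Train
trajectories are normalized to the pre-train 0.1 Hz baseline mean, not to
the first train response — the alternative is one config switch away.
Plasticity time courses normalize to the baseline-epoch mean (so the
baseline averages exactly 100%), summarize the standard report windows
(51–60 min post-HFS, 41–50 min after the de-potentiation train, 35–40 min
post-LFS) as mean ± SEM with the slice as the statistical unit, and gate on
baseline drift (linear fit, flag beyond 5% per 10 min — "stable baseline"
is asserted in practice but rarely defined; this makes it explicit).
Fiber-volley trajectories exclude sweeps whose FV sits at the noise floor
and report the exclusion count; an all-excluded series is an error.

## Molecular quantifications

`ddcq()` averages technical replicates on the Cq scale before any
exponentiation, forms $\Delta Cq$ per sample against the reference gene,
anchors $\Delta\Delta Cq$ at the **mean** $\Delta Cq$ of the named reference
group (a group-level anchor, matching how transgene abundance is normalized
to one region; per-sample anchoring was the plausible alternative), and
returns $2^{-\Delta\Delta Cq}$. It assumes 100% amplification efficiency —
no efficiency correction is attempted. Densitometry is
background-corrected target over background-corrected β-actin, replicates
averaged per sample before group statistics; a non-positive net actin
density is an error, not a ratio.

The imaging ratio implements the thresholded-intensity definition
literally: total VGLUT1 fluorescence over pixels above the VGLUT1
threshold, divided by the count of pixels above the MAP2 threshold.
Thresholds are data, chosen by a blinded observer, and are recorded in the
output for provenance; `auto_thresholds()` (median + 6·MAD noise ceiling)
exists for automated tests, flagged as not blinded. A config option
restricts VGLUT1 pixels to the MAP2 mask for the stricter
"puncta on identified neurites" reading; the default counts all
above-threshold VGLUT1 pixels. The DAPI channel is ignored.

## Statistics

Group comparisons use the pooled-variance two-tailed Student's t
(`welch = TRUE` switches to Welch; Student is the default because that is
the test named in the workflows this package serves), one-way ANOVA with
Tukey HSD for ≥3 groups, mean ± SEM reporting, and star thresholds
0.05/0.01/0.001. No multiple-testing correction is applied across separate
comparisons, mirroring the per-comparison convention; zero-variance
degenerate inputs follow fixed conventions (p = 1 for equal means, p = 0
flagged by an infinite statistic otherwise). `run_pipeline()` validates the
whole manifest before computing anything, records a manifest digest and all
seeds in its run log, writes no timestamps, and is byte-identical across
re-runs — determinism is part of the contract, not an aspiration.

## What the synthetic data does and does not show

The generators reproduce the *geometry* of the real signals — RC
subthreshold responses, ramp firing with adaptation, the artifact/FV/fPSP
anatomy, facilitation/depression trains, exponential plasticity onsets,
dendrite-plus-puncta image structure, duplicate Cq structure — with
additive Gaussian noise and exact ground truth. They do not emulate
electrode drift, series-resistance changes, seal instability, biological
AP waveform diversity (the AdEx spike is truncated, so half-width and fAHP
on synthetic spikes are not biological numbers), correlated or
multiplicative noise, uneven illumination, or amplification-efficiency
variation in qPCR. Passing the closure suite therefore demonstrates that
the estimators are correct and stable on well-formed inputs at realistic
SNR; it does not certify robustness to every artifact of a rig. The
degenerate-input errors (contaminated baselines, truncated sweeps, noise-
floor responses, unstable baselines) are the guard rails for those cases.

The verification problem sizes — an 18-cell passive grid, 20 constructed AP
shapes, the 5-ISI × 5-frequency protocol grid with 100-pulse trains, three
128×128 image pairs, 10,000-replicate null simulations — were chosen so the
whole suite exercises every code path at full acquisition rate while
remaining quick to run on a laptop.

## Known limitations

- No conductance-based (Hodgkin–Huxley) modelling; AdEx waveform features
  above threshold are not biological.
- No vendor binary readers in core; the delimited + JSON sidecar dialect is
  the reference format.
- No current-source-density analysis, no spike sorting, no voltage-clamp
  current analysis.
- The biphasic augmentation sometimes seen during 5 Hz trains has no
  quantitative model here; the renderer's per-pulse FV/amplitude scale
  vectors are the hook for emulating such envelopes, without claiming a
  parameterization.
- `io_curve()` accepts two-point curves for interpolation although ≥4
  intensities are the practical minimum for a usable input–output relation.
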