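# Synthetic extracellular field sweeps: stimulus artifact + fiber volley +
# fPSP, driven by the dynamic-synapse amplitude vector.

#' Field-sweep waveform kinetics
#'
#' Shape parameters of the rendered sweep anatomy. The fiber volley is a
#' fixed Gaussian-shaped negativity; the fPSP is a difference of
#' exponentials; the artifact a brief biphasic transient. All deflections
#' are negative-going, as in stratum radiatum recordings; amplitudes are
#' stated as positive magnitudes.
#'
#' @param fv_amp Fiber-volley trough depth (mV); about 0.5 mV at baseline
#'   intensities in FV-isolation experiments.
#' @param fv_latency Stimulus-to-FV-trough latency (ms).
#' @param fv_width FV full width at half maximum (ms).
#' @param fpsp_amp fPSP peak magnitude for relative amplitude 1 (mV).
#' @param fpsp_latency Stimulus-to-fPSP-onset latency (ms); must exceed
#'   \code{fv_latency}.
#' @param fpsp_tau_rise,fpsp_tau_decay fPSP kernel time constants (ms).
#' @param artifact_amp Artifact magnitude (mV).
#' @param artifact_ms Artifact duration (ms).
#' @param noise_sd Additive Gaussian noise SD (mV).
#' @return An object of class \code{"field_kinetics"}.
#' @export
field_kinetics <- function(fv_amp = 0.5, fv_latency = 1.5, fv_width = 1,
                           fpsp_amp = 1.5, fpsp_latency = 3,
                           fpsp_tau_rise = 1.5, fpsp_tau_decay = 12,
                           artifact_amp = 5, artifact_ms = 0.4,
                           noise_sd = 0) {
  stopifnot(fv_latency > 0, fv_width > 0, fpsp_latency > fv_latency,
            fpsp_tau_rise > 0, fpsp_tau_decay > fpsp_tau_rise,
            fv_amp >= 0, fpsp_amp > 0, noise_sd >= 0)
  structure(list(fv_amp = fv_amp, fv_latency = fv_latency,
                 fv_width = fv_width, fpsp_amp = fpsp_amp,
                 fpsp_latency = fpsp_latency,
                 fpsp_tau_rise = fpsp_tau_rise,
                 fpsp_tau_decay = fpsp_tau_decay,
                 artifact_amp = artifact_amp, artifact_ms = artifact_ms,
                 noise_sd = noise_sd),
            class = "field_kinetics")
}

#' Unit fPSP kernel
#'
#' Difference-of-exponentials kernel normalized to unit peak magnitude,
#' evaluated at times \code{t_ms} after fPSP onset (zero before onset).
#'
#' @param t_ms Times after fPSP onset (ms).
#' @param kinetics A \code{\link{field_kinetics}} record.
#' @return Kernel values in [0, 1].
#' @export
fpsp_kernel <- function(t_ms, kinetics) {
  tr <- kinetics$fpsp_tau_rise; td <- kinetics$fpsp_tau_decay
  raw <- ifelse(t_ms <= 0, 0, exp(-t_ms / td) - exp(-t_ms / tr))
  t_pk <- td * tr / (td - tr) * log(td / tr)
  raw / (exp(-t_pk / td) - exp(-t_pk / tr))
}

#' Time of the fPSP peak after stimulus onset (ms)
#' @param kinetics A \code{\link{field_kinetics}} record.
#' @return Peak latency from stimulus onset (ms).
#' @export
fpsp_peak_time <- function(kinetics) {
  tr <- kinetics$fpsp_tau_rise; td <- kinetics$fpsp_tau_decay
  kinetics$fpsp_latency + td * tr / (td - tr) * log(td / tr)
}

#' Render a field sweep from relative response amplitudes
#'
#' Renders one continuous multi-stimulus sweep: for every stimulus a brief
#' biphasic artifact, a fixed fiber volley (optionally scaled per pulse) and
#' an fPSP whose peak is \code{fpsp_amp} times the pulse's relative
#' amplitude, plus additive Gaussian noise. Ground-truth landmark times and
#' amplitudes are attached for closure testing.
#'
#' @param amplitudes Positive relative fPSP amplitudes, one per stimulus.
#' @param kinetics A \code{\link{field_kinetics}} record.
#' @param protocol \code{protocol_spec} of kind \code{paired_pulse},
#'   \code{train} or \code{baseline}; determines stimulus times.
#' @param seed Integer seed for the noise.
#' @param fv_scale Optional per-pulse fiber-volley scale vector (defaults to
#'   1 for every pulse; the FV is otherwise independent of train position).
#' @param dt Sampling interval (s).
#' @param pre_s Quiet time before the first stimulus (s).
#' @param stim_intensity Stimulation intensity bookkeeping (uA).
#' @return A \code{field_sweep}; \code{meta$truth} holds the generating
#'   amplitudes and kinetics, \code{landmarks} the per-stimulus ground-truth
#'   times. A warning is recorded in \code{meta$overlap_warning} when the
#'   fPSP peak of one stimulus falls after the next stimulus.
#' @export
synthesize_field_sweeps <- function(amplitudes, kinetics, protocol,
                                    seed = 1L, fv_scale = NULL, dt = 5e-5,
                                    pre_s = 0.01, stim_intensity = NA_real_) {
  stopifnot(inherits(kinetics, "field_kinetics"),
            inherits(protocol, "protocol_spec"), all(amplitudes > 0))
  p <- protocol$params
  rel_times <- switch(protocol$kind,
    paired_pulse = c(0, p$isi / 1000),
    train = (seq_len(p$n_pulses) - 1) / p$frequency,
    baseline = 0,
    stop("unsupported protocol kind for field synthesis: ", protocol$kind))
  n_stim <- length(rel_times)
  if (length(amplitudes) != n_stim)
    stop(sprintf("need %d amplitudes for this protocol, got %d",
                 n_stim, length(amplitudes)))
  if (is.null(fv_scale)) fv_scale <- rep(1, n_stim)
  stopifnot(length(fv_scale) == n_stim)

  stim_times <- pre_s + rel_times
  peak_lat_s <- fpsp_peak_time(kinetics) / 1000
  overlap <- n_stim > 1 && any(diff(stim_times) < peak_lat_s)

  tail_s <- (kinetics$fpsp_latency + 6 * kinetics$fpsp_tau_decay) / 1000 + 0.01
  total_s <- stim_times[n_stim] + tail_s
  n <- ceiling(total_s / dt)
  tt_ms <- (seq_len(n) - 1) * dt * 1000
  v <- numeric(n)

  sigma <- kinetics$fv_width / (2 * sqrt(2 * log(2)))
  for (k in seq_len(n_stim)) {
    s_ms <- stim_times[k] * 1000
    # artifact: one biphasic cycle
    art <- tt_ms >= s_ms & tt_ms < s_ms + kinetics$artifact_ms
    v[art] <- v[art] + kinetics$artifact_amp *
      sin(2 * pi * (tt_ms[art] - s_ms) / kinetics$artifact_ms)
    # fiber volley: Gaussian negativity, local support
    fv_ctr <- s_ms + kinetics$fv_latency
    loc <- tt_ms >= fv_ctr - 5 * sigma & tt_ms <= fv_ctr + 5 * sigma
    v[loc] <- v[loc] - fv_scale[k] * kinetics$fv_amp *
      exp(-(tt_ms[loc] - fv_ctr)^2 / (2 * sigma^2))
    # fPSP
    on_ms <- s_ms + kinetics$fpsp_latency
    sup <- tt_ms > on_ms & tt_ms <= on_ms + 8 * kinetics$fpsp_tau_decay
    v[sup] <- v[sup] - amplitudes[k] * kinetics$fpsp_amp *
      fpsp_kernel(tt_ms[sup] - on_ms, kinetics)
  }
  if (kinetics$noise_sd > 0)
    v <- v + with_seed(seed, rnorm(n, 0, kinetics$noise_sd))

  landmarks <- lapply(seq_len(n_stim), function(k) list(
    artifact_window = stim_times[k] + c(0, kinetics$artifact_ms / 1000),
    fv_trough = stim_times[k] + kinetics$fv_latency / 1000,
    fpsp_peak = stim_times[k] + peak_lat_s))
  field_sweep(v, dt = dt, stim_times = stim_times,
              stim_intensity = stim_intensity, landmarks = landmarks,
              meta = list(protocol = protocol,
                          truth = list(amplitudes = amplitudes,
                                       fv_scale = fv_scale,
                                       kinetics = kinetics),
                          overlap_warning = overlap))
}

#' Synthetic plasticity time course
#'
#' Per-sweep baseline-normalized responses at 0.1 Hz pacing: flat at
#' \code{pre_level} during the baseline epoch, then an exponential approach
#' from \code{pre_level} to \code{post_level} after induction at t = 0.
#'
#' @param pre_level,post_level Response levels (baseline units, > 0).
#' @param tau_onset Time constant of the post-induction approach (min).
#' @param protocol Induction \code{protocol_spec} (bookkeeping; carried in
#'   the output attributes).
#' @param noise_sd Multiplicative Gaussian noise SD (fraction of level).
#' @param seed Integer seed.
#' @param baseline_min Baseline duration before induction (min).
#' @param followup_min Follow-up duration after induction (min).
#' @param rate_hz Sweep rate (Hz); 0.1 Hz as in baseline pacing.
#' @return A \code{data.frame} (class \code{"plasticity_series"}) with
#'   columns \code{t_min} and \code{value}; attributes \code{epochs} and
#'   \code{truth}.
#' @export
simulate_plasticity_timecourse <- function(pre_level, post_level, tau_onset,
                                           protocol = NULL, noise_sd = 0,
                                           seed = 1L, baseline_min = 10,
                                           followup_min = 60,
                                           rate_hz = 0.1) {
  stopifnot(pre_level > 0, post_level > 0, tau_onset > 0)
  step_min <- 1 / (rate_hz * 60)
  t_min <- seq(-baseline_min, followup_min, by = step_min)
  value <- ifelse(t_min <= 0, pre_level,
                  pre_level + (post_level - pre_level) *
                    (1 - exp(-t_min / tau_onset)))
  if (noise_sd > 0)
    value <- value * (1 + with_seed(seed, rnorm(length(value), 0, noise_sd)))
  out <- data.frame(t_min = t_min, value = value)
  attr(out, "epochs") <- list(baseline = c(-baseline_min, 0),
                              followup = c(0, followup_min))
  attr(out, "truth") <- list(pre_level = pre_level, post_level = post_level,
                             tau_onset = tau_onset, protocol = protocol)
  class(out) <- c("plasticity_series", "data.frame")
  out
}
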