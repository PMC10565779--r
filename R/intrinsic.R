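# Intrinsic excitability: passive membrane properties, ramp firing and AP
# waveform features from current-clamp traces.

#' Analysis configuration for current-clamp traces
#'
#' @param dvdt_thresh Spike-detection criterion: upward dV/dt crossing
#'   (mV/ms). The conventional 20 mV/ms by default.
#' @param refractory_ms Minimum separation between detections (ms).
#' @param sg_window Savitzky-Golay window (samples, odd) used to smooth the
#'   voltage derivative before phase-plane analysis; 7 samples at 20 kHz.
#' @param sg_order Polynomial order of the smoother.
#' @param fahp_window_ms Post-peak search window for the fast
#'   afterhyperpolarization (ms).
#' @param junction_offset_mV Liquid-junction correction applied before
#'   measuring RMP (0 = already corrected).
#' @return A list of class \code{"intrinsic_config"}.
#' @export
intrinsic_config <- function(dvdt_thresh = 20, refractory_ms = 2,
                             sg_window = 7, sg_order = 3,
                             fahp_window_ms = 20, junction_offset_mV = 0) {
  stopifnot(dvdt_thresh > 0, refractory_ms >= 0, sg_window %% 2 == 1,
            sg_order < sg_window)
  structure(list(dvdt_thresh = dvdt_thresh, refractory_ms = refractory_ms,
                 sg_window = sg_window, sg_order = sg_order,
                 fahp_window_ms = fahp_window_ms,
                 junction_offset_mV = junction_offset_mV),
            class = "intrinsic_config")
}

# Smoothed first derivative (mV/ms) via Savitzky-Golay differentiation.
.dvdt <- function(v, dt_ms, config) {
  n <- length(v)
  if (n < config$sg_window) {
    return(c(diff(v) / dt_ms, 0))
  }
  signal::sgolayfilt(v, p = config$sg_order, n = config$sg_window,
                     m = 1, ts = dt_ms)
}

#' Resting membrane potential
#'
#' Mean voltage over a pre-stimulus window. The window must precede any
#' stimulus and be at least 100 ms long; a window containing spikes is
#' rejected as a contaminated baseline.
#'
#' @param trace A \code{trace}.
#' @param window Numeric length-2 time window (s); defaults to the full
#'   pre-stimulus epoch recorded in \code{meta$stim_onset}.
#' @param config An \code{\link{intrinsic_config}}.
#' @return RMP in mV.
#' @export
measure_rmp <- function(trace, window = NULL,
                        config = intrinsic_config()) {
  stopifnot(inherits(trace, "trace"))
  if (config$junction_offset_mV != 0)
    trace <- liquid_junction_correct(trace, config$junction_offset_mV)
  onset <- trace$meta$stim_onset
  if (is.null(window)) {
    if (is.null(onset)) stop("no window given and no stimulus onset in meta")
    window <- c(trace$t0, onset)
  }
  if (diff(window) < 0.1) stop("baseline window must be >= 100 ms")
  if (!is.null(onset) && window[2] > onset + trace$dt / 2)
    stop("baseline window overlaps the stimulus")
  tt <- trace_times(trace)
  sel <- tt >= window[1] & tt < window[2]
  if (!any(sel)) stop("baseline window outside trace span")
  seg <- voltage_trace(trace$v[sel], trace$dt)
  det <- detect_spikes(seg, config)
  # a genuine AP tops the local baseline by tens of mV; derivative crossings
  # from recording noise alone do not contaminate the window
  if (length(det$peak_times)) {
    pk_v <- seg$v[round((det$peak_times - seg$t0) / seg$dt) + 1L]
    if (any(pk_v > stats::median(seg$v) + 10))
      stop("contaminated baseline: spikes detected in RMP window")
  }
  mean(trace$v[sel])
}

#' Detect action potentials
#'
#' Spikes are upward crossings of the dV/dt criterion with refractory
#' enforcement; each detection carries a waveform segment spanning
#' [peak - 5 ms, peak + 20 ms], clipped to the trace.
#'
#' @param trace A \code{trace} (sampling interval must be <= 0.1 ms).
#' @param config An \code{\link{intrinsic_config}}.
#' @return List with \code{times} (criterion crossing times, s),
#'   \code{peak_times} (s), and \code{segments} (list of \code{trace}
#'   objects, each with \code{meta$peak_idx}).
#' @export
detect_spikes <- function(trace, config = intrinsic_config()) {
  stopifnot(inherits(trace, "trace"))
  if (trace$dt > 1e-4 + 1e-12) stop("sampling interval must be <= 0.1 ms")
  dt_ms <- trace$dt * 1000
  dvdt <- .dvdt(trace$v, dt_ms, config)
  up <- which(dvdt[-1] >= config$dvdt_thresh &
              dvdt[-length(dvdt)] < config$dvdt_thresh) + 1L
  # refractory: drop crossings closer than refractory_ms to the last accepted
  keep <- integer(0)
  last_t <- -Inf
  for (k in up) {
    tk <- k * dt_ms
    if (tk - last_t >= config$refractory_ms) {
      keep <- c(keep, k)
      last_t <- tk
    }
  }
  tt <- trace_times(trace)
  n <- length(trace$v)
  half_pre <- round(5e-3 / trace$dt)
  post <- round(20e-3 / trace$dt)
  peak_idx <- vapply(keep, function(k) {
    k2 <- min(n, k + round(5e-3 / trace$dt))
    (k:k2)[which.max(trace$v[k:k2])]
  }, integer(1))
  segments <- lapply(peak_idx, function(pk) {
    a <- max(1L, pk - half_pre); b <- min(n, pk + post)
    voltage_trace(trace$v[a:b], trace$dt, t0 = tt[a],
          meta = list(peak_idx = pk - a + 1L))
  })
  list(times = tt[keep], peak_times = tt[peak_idx], segments = segments)
}

#' Phase-plane action-potential threshold
#'
#' Computes the smoothed first derivative of voltage, forms the phase-plane
#' curve dV/dt versus V along the upstroke (segment start to the dV/dt
#' maximum), resamples that curve onto a uniform dense voltage grid, and
#' returns the voltage at which its slope, d(dV/dt)/dV estimated by central
#' finite differences on the grid, is maximal. The uniform grid avoids the
#' small-denominator noise a nonuniform voltage spacing would inject into
#' the finite differences.
#'
#' @param segment A spike segment from \code{\link{detect_spikes}}.
#' @param config An \code{\link{intrinsic_config}}.
#' @param grid_mV Voltage grid step for the phase-plane resampling (mV).
#' @return Threshold voltage (mV). Also returns, as attributes,
#'   \code{"index"} (sample index of the threshold point in the segment) and
#'   \code{"dvdt"} (the smoothed derivative, mV/ms).
#' @export
ap_threshold <- function(segment, config = intrinsic_config(),
                         grid_mV = 0.1) {
  stopifnot(inherits(segment, "trace"))
  dt_ms <- segment$dt * 1000
  dvdt <- .dvdt(segment$v, dt_ms, config)
  up_end <- which.max(dvdt)
  # drop the smoother's half-window next to the dV/dt peak (filter edge)
  up_end <- up_end - (config$sg_window %/% 2)
  if (up_end < 5L) stop("threshold undefined: upstroke too short")
  v <- segment$v[1:up_end]; g <- dvdt[1:up_end]
  # keep the strictly rising part of the trajectory so V is a valid abscissa
  keep <- c(TRUE, diff(cummax(v)) > 0)
  v <- v[keep]; g <- g[keep]
  if (length(v) < 5L || diff(range(v)) < 5 * grid_mV)
    stop("threshold undefined: upstroke spans too little voltage")
  # phase-plane curve dV/dt vs V on a uniform dense voltage grid; the
  # threshold is V at the maximum of d(dV/dt)/dV by central differences
  vg <- seq(v[1], v[length(v)], by = grid_mV)
  gg <- stats::spline(v, g, xout = vg, method = "fmm")$y
  slope <- (gg[-(1:2)] - gg[1:(length(gg) - 2)]) / (2 * grid_mV)
  if (!length(slope) || all(!is.finite(slope)))
    stop("threshold undefined: degenerate phase plane")
  rng <- range(slope, finite = TRUE)
  if (diff(rng) < 1e-6 * max(1, abs(rng[2])))
    stop("threshold undefined: constant phase-plane slope")
  i_max <- which.max(slope) + 1L
  thr <- vg[i_max]
  # nearest sample index on the upstroke, for time-of-threshold lookups
  i_thr <- which.min(abs(segment$v[1:up_end] - thr))
  structure(thr, index = i_thr, dvdt = dvdt)
}

#' Action-potential waveform features
#'
#' Amplitude is threshold-to-peak; half-width is the time between the two
#' crossings of threshold + amplitude/2, linearly interpolated between
#' samples; the maximal rise slope is the largest smoothed dV/dt on the
#' upstroke; the fast afterhyperpolarization is referenced to threshold and
#' searched within a post-peak window, with its delay measured from the peak.
#'
#' @param segment A spike segment from \code{\link{detect_spikes}}.
#' @param threshold AP threshold (mV); computed via \code{\link{ap_threshold}}
#'   when omitted.
#' @param config An \code{\link{intrinsic_config}}.
#' @return A one-row \code{data.frame} of class \code{"spike_features"}:
#'   \code{threshold}, \code{amplitude}, \code{half_width},
#'   \code{max_rise_slope}, \code{fahp_amp}, \code{fahp_delay} (NA when no
#'   post-peak minimum below threshold is found within the window).
#' @export
ap_features <- function(segment, threshold = NULL,
                        config = intrinsic_config()) {
  stopifnot(inherits(segment, "trace"))
  if (is.null(threshold)) threshold <- ap_threshold(segment, config)
  dt_ms <- segment$dt * 1000
  v <- segment$v
  pk <- segment$meta$peak_idx
  if (is.null(pk)) pk <- which.max(v)
  vpeak <- v[pk]
  if (threshold >= vpeak) stop("threshold must lie below the peak")
  amplitude <- vpeak - threshold
  half_level <- threshold + amplitude / 2

  cross_up <- .interp_crossing(v, half_level, 1:pk, rising = TRUE)
  cross_dn <- .interp_crossing(v, half_level, pk:length(v), rising = FALSE)
  half_width <- if (is.na(cross_up) || is.na(cross_dn)) NA_real_
                else (cross_dn - cross_up) * dt_ms

  # maximal rise slope from raw sample differences: the smoothed derivative
  # rings at sharp corners and would overshoot on fast upstrokes
  max_rise <- max(diff(v[1:pk])) / dt_ms

  w <- min(length(v), pk + round(config$fahp_window_ms / dt_ms))
  fahp_amp <- NA_real_; fahp_delay <- NA_real_
  if (w > pk + 1L) {
    post <- v[(pk + 1L):w]
    i_min <- which.min(post)
    # require an interior minimum below threshold
    if (post[i_min] < threshold - 1e-9 && i_min < length(post)) {
      fahp_amp <- threshold - post[i_min]
      fahp_delay <- i_min * dt_ms
    }
  }
  out <- data.frame(threshold = as.numeric(threshold), amplitude = amplitude,
                    half_width = half_width, max_rise_slope = max_rise,
                    fahp_amp = fahp_amp, fahp_delay = fahp_delay)
  class(out) <- c("spike_features", "data.frame")
  out
}

# Linearly interpolated index (in samples, 1-based fractional) where v
# crosses `level` within idx, in the stated direction; NA if never.
.interp_crossing <- function(v, level, idx, rising = TRUE) {
  x <- v[idx]
  if (rising) {
    k <- which(x[-length(x)] < level & x[-1] >= level)
  } else {
    k <- which(x[-length(x)] >= level & x[-1] < level)
  }
  if (!length(k)) return(NA_real_)
  k <- k[1]
  frac <- (level - x[k]) / (x[k + 1] - x[k])
  idx[k] + frac
}

#' Analyze a depolarizing current ramp
#'
#' Counts spikes during the ramp epoch and determines the rheobase as the
#' injected current, by the linear time-to-current map of the ramp, at the
#' first AP's threshold-crossing time (the phase-plane threshold point).
#' When the ramp evokes no spike the rheobase is NA and \code{n_spikes} 0.
#'
#' @param trace A \code{trace}; ramp onset is taken from
#'   \code{meta$stim_onset} or, failing that, from the first change in
#'   \code{i_cmd}.
#' @param protocol \code{protocol_spec} of kind \code{ramp} (defaults to the
#'   one in \code{meta$protocol}).
#' @param config An \code{\link{intrinsic_config}}.
#' @return List of class \code{"ramp_result"}: \code{n_spikes},
#'   \code{rheobase} (pA), \code{spike_times} (s), \code{from_potential}
#'   (mV, mean over the 100 ms preceding the ramp).
#' @export
analyze_ramp <- function(trace, protocol = NULL,
                         config = intrinsic_config()) {
  stopifnot(inherits(trace, "trace"))
  if (is.null(protocol)) protocol <- trace$meta$protocol
  if (is.null(protocol) || protocol$kind != "ramp")
    stop("protocol error: ramp protocol metadata required")
  p <- protocol$params
  onset <- trace$meta$stim_onset
  if (is.null(onset)) {
    if (is.null(trace$i_cmd)) stop("protocol error: no ramp onset available")
    j <- which(trace$i_cmd != trace$i_cmd[1])[1]
    if (is.na(j)) stop("protocol error: flat i_cmd, no ramp found")
    onset <- trace$t0 + (j - 1) * trace$dt
  }
  ramp_end <- onset + p$duration

  det <- detect_spikes(trace, config)
  in_ramp <- det$times >= onset & det$times <= ramp_end
  spike_times <- det$times[in_ramp]
  n_spikes <- length(spike_times)

  tt <- trace_times(trace)
  pre <- tt >= onset - 0.1 & tt < onset
  from_potential <- if (any(pre)) mean(trace$v[pre]) else NA_real_

  rheobase <- NA_real_
  if (n_spikes > 0) {
    seg <- det$segments[in_ramp][[1]]
    thr <- tryCatch(ap_threshold(seg, config), error = function(e) NULL)
    t_thr <- if (!is.null(thr)) seg$t0 + (attr(thr, "index") - 1) * seg$dt
             else spike_times[1]
    rheobase <- p$i_start +
      (p$i_end - p$i_start) * (t_thr - onset) / p$duration
    rheobase <- min(max(rheobase, p$i_start), p$i_end)
  }
  structure(list(n_spikes = n_spikes, rheobase = rheobase,
                 spike_times = spike_times, from_potential = from_potential),
            class = "ramp_result")
}

#' @export
print.ramp_result <- function(x, ...) {
  cat(sprintf("<ramp_result> %d spikes, rheobase %s pA, from %.2f mV\n",
              x$n_spikes,
              if (is.na(x$rheobase)) "NA" else sprintf("%.1f", x$rheobase),
              x$from_potential))
  invisible(x)
}

#' Passive membrane properties from a subthreshold current step
#'
#' Input resistance is the steady-state voltage deflection divided by the
#' step current; the membrane time constant comes from a single-exponential
#' fit to the relaxation after step onset; capacitance is tau_m / R_N.
#'
#' @param trace A subthreshold \code{trace} with step metadata.
#' @param protocol \code{protocol_spec} of kind \code{step} or
#'   \code{membrane_test} (defaults to \code{meta$protocol}).
#' @param config An \code{\link{intrinsic_config}}.
#' @return List of class \code{"passive_props"}: \code{rmp} (mV), \code{r_n}
#'   (MOhm), \code{tau_m} (ms), \code{c_m} (pF).
#' @export
passive_from_step <- function(trace, protocol = NULL,
                              config = intrinsic_config()) {
  stopifnot(inherits(trace, "trace"))
  if (is.null(protocol)) protocol <- trace$meta$protocol
  if (is.null(protocol) || !protocol$kind %in% c("step", "membrane_test"))
    stop("protocol error: step protocol metadata required")
  amp <- protocol$params$amplitude
  if (amp == 0) stop("undefined r_n: step amplitude is zero")
  onset <- trace$meta$stim_onset
  if (is.null(onset)) stop("protocol error: no step onset in meta")
  dur <- protocol$params$duration
  if (protocol$kind == "membrane_test") dur <- dur / 2 # first phase only
  tt <- trace_times(trace)

  if (length(detect_spikes(trace, config)$times) > 0)
    stop("step response is not subthreshold")

  v0 <- mean(trace$v[tt >= onset - 0.1 & tt < onset])
  ss_win <- tt >= onset + 0.8 * dur & tt < onset + dur
  v_ss <- mean(trace$v[ss_win])
  dv <- v_ss - v0
  r_n <- 1000 * dv / amp # mV/pA -> GOhm -> MOhm

  # single-exponential fit to the relaxation
  rel <- which(tt >= onset & tt < onset + dur)
  t_ms <- (tt[rel] - onset) * 1000
  y <- trace$v[rel]
  tau0 <- {
    target <- v0 + (1 - exp(-1)) * dv
    k <- if (dv < 0) which(y <= target)[1] else which(y >= target)[1]
    if (is.na(k)) dur * 250 else max(t_ms[k], 5 * trace$dt * 1000)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ vss + (v0f - vss) * exp(-t_ms / tau),
                      start = list(vss = v_ss, v0f = v0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  tau_m <- if (!is.null(fit)) coef(fit)[["tau"]] else {
    # log-linear fallback on the early relaxation
    resid <- abs(y - v_ss)
    sel <- which(resid > 0.02 * abs(dv))
    if (length(sel) < 5) stop("fit error: exponential relaxation fit failed")
    -1 / stats::lm.fit(cbind(1, t_ms[sel]), log(resid[sel]))$coefficients[2]
  }
  c_m <- 1000 * tau_m / abs(r_n) # ms/MOhm -> nF -> pF
  structure(list(rmp = v0, r_n = abs(r_n), tau_m = tau_m, c_m = c_m),
            class = "passive_props")
}

#' @export
print.passive_props <- function(x, ...) {
  cat(sprintf("<passive_props> RMP %.2f mV, R_N %.1f MOhm, tau_m %.2f ms, C %.1f pF\n",
              x$rmp, x$r_n, x$tau_m, x$c_m))
  invisible(x)
}
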