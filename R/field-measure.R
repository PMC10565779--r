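# Field-potential quantification: sweep landmarks, input-output curves,
# paired-pulse ratios, trains, plasticity time courses, FV trajectories.

#' Field-sweep measurement configuration
#'
#' @param artifact_ms Blanked window after each stimulus onset (ms).
#' @param fv_window_ms Fiber-volley trough search window after stimulus (ms).
#' @param fpsp_window_ms fPSP extremum search window after stimulus (ms);
#'   clipped at the next stimulus.
#' @param baseline_ms Local pre-stimulus baseline window (ms).
#' @param slope_frac Rising-phase bounds for the slope fit (fractions of the
#'   fPSP peak, default 20-80%).
#' @param overlap Either \code{"subtract"} (peel each measured fPSP with a
#'   template before measuring later stimuli; required at short intervals) or
#'   \code{"none"}.
#' @param template_kinetics Optional \code{\link{field_kinetics}} providing
#'   the analytic unit fPSP template for peeling.
#' @param template Optional sampled unit-peak template (numeric, starting at
#'   stimulus onset, at the sweep's sampling interval), e.g. from an
#'   averaged isolated baseline response; used when
#'   \code{template_kinetics} is absent.
#' @param noise_floor Smallest trustworthy fPSP/FV magnitude (mV).
#' @return A list of class \code{"field_config"}.
#' @export
field_config <- function(artifact_ms = 0.5, fv_window_ms = c(0.5, 2.5),
                         fpsp_window_ms = c(2.5, 100), baseline_ms = 2,
                         slope_frac = c(0.2, 0.8), overlap = "subtract",
                         template_kinetics = NULL, template = NULL,
                         noise_floor = 0.02) {
  overlap <- match.arg(overlap, c("subtract", "none"))
  stopifnot(slope_frac[1] > 0, slope_frac[2] < 1,
            slope_frac[1] < slope_frac[2])
  structure(list(artifact_ms = artifact_ms, fv_window_ms = fv_window_ms,
                 fpsp_window_ms = fpsp_window_ms, baseline_ms = baseline_ms,
                 slope_frac = slope_frac, overlap = overlap,
                 template_kinetics = template_kinetics, template = template,
                 noise_floor = noise_floor),
            class = "field_config")
}

#' Measure fiber volley and fPSP on a field sweep
#'
#' For every stimulus, in time order: the artifact window is blanked; the
#' fiber-volley amplitude is the local-baseline-to-trough depth in the FV
#' window; the fPSP amplitude is baseline-to-extremum in the fPSP window
#' (clipped at the next stimulus); the slope is the least-squares line
#' through the samples between the 20% and 80% crossings of the rising
#' phase. With \code{overlap = "subtract"} each measured fPSP is peeled off
#' with a unit template before the next stimulus is measured, so closely
#' spaced responses do not contaminate one another. Magnitudes are positive
#' (negative-going convention).
#'
#' @param sweep A \code{field_sweep}.
#' @param config A \code{\link{field_config}}. A sweep produced by
#'   \code{\link{synthesize_field_sweeps}} supplies its own kinetics as the
#'   default template.
#' @return A \code{data.frame} with one row per stimulus: \code{stim_time}
#'   (s), \code{fv_amp}, \code{fpsp_amp} (mV), \code{fpsp_slope} (mV/ms),
#'   \code{stim_intensity} (uA), \code{truncated} (logical).
#' @export
measure_sweep <- function(sweep, config = field_config()) {
  stopifnot(inherits(sweep, "field_sweep"))
  dt_ms <- sweep$dt * 1000
  tt_ms <- (trace_times(sweep) - sweep$t0) * 1000
  stim_ms <- (sweep$stim_times - sweep$t0) * 1000
  n_stim <- length(stim_ms)
  v <- sweep$v

  tk <- config$template_kinetics
  if (is.null(tk) && is.null(config$template) &&
      config$overlap == "subtract" && !is.null(sweep$meta$truth))
    tk <- sweep$meta$truth$kinetics

  out <- data.frame(stim_time = sweep$stim_times, fv_amp = NA_real_,
                    fpsp_amp = NA_real_, fpsp_slope = NA_real_,
                    stim_intensity = sweep$stim_intensity,
                    truncated = FALSE)
  for (k in seq_len(n_stim)) {
    s <- stim_ms[k]
    nxt <- if (k < n_stim) stim_ms[k + 1] else Inf
    base_sel <- tt_ms >= s - config$baseline_ms & tt_ms < s
    b <- if (any(base_sel)) mean(v[base_sel]) else 0

    fv_sel <- which(tt_ms >= s + config$fv_window_ms[1] &
                    tt_ms <= s + config$fv_window_ms[2])
    out$fv_amp[k] <- if (length(fv_sel)) b - min(v[fv_sel]) else NA_real_

    hi <- min(s + config$fpsp_window_ms[2], nxt - dt_ms / 2)
    fp_sel <- which(tt_ms >= s + config$fpsp_window_ms[1] & tt_ms <= hi)
    if (!length(fp_sel)) { out$truncated[k] <- TRUE; next }
    i_min <- fp_sel[which.min(v[fp_sel])]
    amp <- b - v[i_min]
    # extremum pinned to a clipped window end means the peak was cut off
    if (is.finite(nxt) && i_min == fp_sel[length(fp_sel)] &&
        hi < s + config$fpsp_window_ms[2])
      out$truncated[k] <- TRUE
    out$fpsp_amp[k] <- amp

    # 20-80% rising-phase slope
    rise_idx <- fp_sel[1]:i_min
    lo_lev <- b - config$slope_frac[1] * amp
    hi_lev <- b - config$slope_frac[2] * amp
    c20 <- .interp_crossing(v, lo_lev, rise_idx, rising = FALSE)
    c80 <- .interp_crossing(v, hi_lev, rise_idx, rising = FALSE)
    if (!is.na(c20) && !is.na(c80) && c80 > c20) {
      # resample the rising phase densely over the exact 20-80% interval so
      # the fit matches the continuous least-squares definition rather than
      # wherever the sample grid happens to truncate it
      span <- max(1L, floor(c20) - 2L):min(length(v), ceiling(c80) + 2L)
      tg <- seq((c20 - 1) * dt_ms, (c80 - 1) * dt_ms, length.out = 200L)
      vg <- stats::spline(tt_ms[span], v[span], xout = tg)$y
      fit <- stats::lm.fit(cbind(1, tg), vg)
      out$fpsp_slope[k] <- abs(fit$coefficients[2])
    }
    # peel this fPSP so later stimuli see a clean residual
    if (config$overlap == "subtract" && is.finite(amp) && amp > 0) {
      if (!is.null(tk)) {
        sup <- which(tt_ms > s + tk$fpsp_latency &
                     tt_ms <= s + tk$fpsp_latency + 8 * tk$fpsp_tau_decay)
        v[sup] <- v[sup] + amp * fpsp_kernel(tt_ms[sup] - s - tk$fpsp_latency, tk)
      } else if (!is.null(config$template)) {
        i0 <- which(tt_ms >= s)[1]
        ii <- i0:min(length(v), i0 + length(config$template) - 1L)
        v[ii] <- v[ii] - amp * config$template[seq_along(ii)]
      }
    }
  }
  out
}

#' Input-output curve and intensity-for-fraction lookup
#'
#' Builds the fPSP amplitude versus stimulus intensity relation and returns
#' the smallest intensity achieving a requested fraction of the maximal
#' response, by monotone linear interpolation. Used to set the working
#' intensity (30% of maximum for LTP, 50% for LTD experiments).
#'
#' @param sweeps List of single-stimulus \code{field_sweep}s at graded
#'   intensities, or a \code{data.frame} with columns \code{intensity} and
#'   \code{amplitude}.
#' @param config A \code{\link{field_config}} (for sweep input).
#' @param tolerance Relative non-monotonicity tolerated before warning.
#' @return List of class \code{"io_curve"}: \code{curve} (data.frame sorted
#'   by intensity) and \code{intensity_for_fraction(fraction)}.
#' @export
io_curve <- function(sweeps, config = field_config(), tolerance = 0.05) {
  if (is.data.frame(sweeps)) {
    df <- sweeps[order(sweeps$intensity), c("intensity", "amplitude")]
  } else {
    m <- lapply(sweeps, measure_sweep, config = config)
    df <- data.frame(intensity = vapply(m, function(x) x$stim_intensity[1],
                                        numeric(1)),
                     amplitude = vapply(m, function(x) x$fpsp_amp[1],
                                        numeric(1)))
    df <- df[order(df$intensity), ]
  }
  if (nrow(df) < 2) stop("need at least two intensities")
  if (any(diff(df$amplitude) < -tolerance * max(df$amplitude)))
    warning("input-output curve is non-monotone beyond tolerance")
  i_max <- which.max(df$amplitude)
  rising <- df[1:i_max, ]
  fn <- function(fraction) {
    stopifnot(fraction > 0)
    target <- fraction * max(df$amplitude)
    if (target > max(rising$amplitude) + 1e-12)
      stop("fraction unreachable on this curve")
    if (target < min(rising$amplitude) - 1e-12)
      stop("fraction below the measured range")
    amp <- cummax(rising$amplitude) # enforce monotone abscissa
    stats::approx(amp, rising$intensity, xout = target, ties = "ordered")$y
  }
  structure(list(curve = df, intensity_for_fraction = fn),
            class = "io_curve")
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first fPSP of a two-stimulus sweep on the
#' configured measure (amplitude by default; slope optional). At short
#' intervals the first response is peeled off by template subtraction before
#' the second is measured (see \code{\link{measure_sweep}}).
#'
#' @param sweep A \code{field_sweep} with exactly two stimuli.
#' @param config A \code{\link{field_config}}.
#' @param measure \code{"amplitude"} or \code{"slope"}.
#' @return The paired-pulse ratio (dimensionless).
#' @export
paired_pulse_ratio <- function(sweep, config = field_config(),
                               measure = c("amplitude", "slope")) {
  measure <- match.arg(measure)
  stopifnot(length(sweep$stim_times) == 2L)
  m <- measure_sweep(sweep, config)
  x <- if (measure == "amplitude") m$fpsp_amp else m$fpsp_slope
  if (is.na(x[1]) || x[1] < config$noise_floor)
    stop("undefined ratio: first fPSP at or below the noise floor")
  x[2] / x[1]
}

#' Summarize a paired-pulse ratio series
#'
#' Induction-period summary used for PP-LFS: the mean of the last
#' \code{n_last} ratios divided by the first ratio.
#'
#' @param pprs Numeric vector of paired-pulse ratios in stimulation order.
#' @param n_last How many trailing ratios to average (default 20).
#' @return Dimensionless summary ratio.
#' @export
ppr_series_summary <- function(pprs, n_last = 20) {
  stopifnot(length(pprs) >= n_last + 1)
  mean(utils::tail(pprs, n_last)) / pprs[1]
}

#' Analyze a stimulus train
#'
#' Normalizes every response of a train to the pre-train baseline response
#' and reports the full trajectory (percent of baseline), the mean of the
#' last \code{n_last} pulses, and the maximal facilitation.
#'
#' @param x A \code{field_sweep} rendered train, or a numeric vector of
#'   measured responses (mV).
#' @param baseline Mean pre-train 0.1 Hz response (same measure/units).
#' @param config A \code{\link{field_config}} (for sweep input).
#' @param measure \code{"amplitude"} or \code{"slope"}.
#' @param n_last Pulses averaged for the steady-state summary (default 10,
#'   i.e. pulses 91-100 of a 100-pulse train).
#' @return List of class \code{"train_result"}: \code{trajectory} (percent),
#'   \code{last_mean}, \code{max_facilitation}, \code{n_pulses}.
#' @export
analyze_train <- function(x, baseline, config = field_config(),
                          measure = c("amplitude", "slope"), n_last = 10) {
  measure <- match.arg(measure)
  if (missing(baseline) || is.null(baseline) || !is.finite(baseline) ||
      baseline <= 0)
    stop("missing or invalid pre-train baseline")
  resp <- if (inherits(x, "field_sweep")) {
    m <- measure_sweep(x, config)
    if (measure == "amplitude") m$fpsp_amp else m$fpsp_slope
  } else as.numeric(x)
  traj <- 100 * resp / baseline
  n <- length(traj)
  structure(list(trajectory = traj,
                 last_mean = mean(traj[max(1, n - n_last + 1):n]),
                 max_facilitation = max(traj),
                 n_pulses = n),
            class = "train_result")
}

#' Frequency tuning curve of short-term plasticity
#'
#' Collects per-frequency maximal facilitation and steady-state (last-10)
#' means into one table.
#'
#' @param trains Named list mapping frequency (Hz, as names) to either a
#'   \code{train_result} or a trajectory vector in percent of baseline.
#' @param n_last Pulses averaged for the steady-state summary.
#' @return A \code{data.frame} of class \code{"tuning_curve"}: columns
#'   \code{frequency}, \code{max_facilitation}, \code{last_mean} (percent).
#' @export
tuning_curve <- function(trains, n_last = 10) {
  freqs <- as.numeric(names(trains))
  if (any(is.na(freqs)) || any(freqs <= 0))
    stop("train names must be positive frequencies (Hz)")
  if (anyDuplicated(freqs)) stop("duplicated frequency in tuning curve input")
  rows <- lapply(seq_along(trains), function(i) {
    tr <- trains[[i]]
    if (!inherits(tr, "train_result"))
      tr <- analyze_train(tr, baseline = 100, n_last = n_last)
    data.frame(frequency = freqs[i],
               max_facilitation = tr$max_facilitation,
               last_mean = tr$last_mean)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$frequency), ]
  rownames(out) <- NULL
  class(out) <- c("tuning_curve", "data.frame")
  out
}

# default report windows (min) per induction protocol
.default_windows <- function(kind) {
  switch(kind,
         hfs = list(post_hfs = c(51, 60)),
         depotentiation = list(post_dp = c(41, 50)),
         pp_lfs = list(post_lfs = c(35, 40)),
         sp_lfs = list(post_lfs = c(35, 40)),
         list(post = c(51, 60)))
}

#' Quantify a plasticity time course
#'
#' Normalizes a timed slope (or amplitude) series to its baseline-epoch mean
#' (in percent, so the baseline averages 100% by construction) and summarizes
#' the configured post-induction windows as mean, SEM and n. A linear drift
#' check over the baseline flags unstable experiments.
#'
#' @param slopes A \code{data.frame} with columns \code{t_min} and
#'   \code{value} (induction at t = 0), e.g. from
#'   \code{\link{simulate_plasticity_timecourse}}.
#' @param protocol Induction \code{protocol_spec}; selects default report
#'   windows (51-60 min after HFS, 41-50 min after de-potentiation, 35-40
#'   min after LFS).
#' @param windows Named list of report windows (min) overriding the default.
#' @param baseline_epoch Baseline window (min), default from the series
#'   attributes or c(-10, 0).
#' @param stability_tol Largest tolerated baseline drift (percent per 10
#'   min) before flagging.
#' @return List of class \code{"plasticity_timecourse"}: \code{series}
#'   (t_min, normalized percent), \code{window_means} (data.frame with mean,
#'   sem, n), \code{baseline_ok}, \code{baseline_drift} (%/10 min),
#'   \code{epochs}.
#' @export
plasticity_quantify <- function(slopes, protocol = NULL, windows = NULL,
                                baseline_epoch = NULL, stability_tol = 5) {
  stopifnot(is.data.frame(slopes), all(c("t_min", "value") %in% names(slopes)))
  if (is.null(baseline_epoch)) {
    ep <- attr(slopes, "epochs")
    baseline_epoch <- if (!is.null(ep)) ep$baseline else c(-10, 0)
  }
  if (is.null(windows)) {
    kind <- if (!is.null(protocol)) protocol$kind else ""
    windows <- .default_windows(kind)
  }
  base_sel <- slopes$t_min >= baseline_epoch[1] & slopes$t_min <= baseline_epoch[2]
  if (!any(base_sel)) stop("no samples in the baseline epoch")
  base_mean <- mean(slopes$value[base_sel])
  normalized <- 100 * slopes$value / base_mean

  drift_fit <- stats::lm.fit(cbind(1, slopes$t_min[base_sel]),
                             normalized[base_sel])
  drift <- drift_fit$coefficients[2] * 10 # percent per 10 min
  wm <- do.call(rbind, lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    sel <- slopes$t_min >= w[1] & slopes$t_min <= w[2]
    vals <- normalized[sel]
    data.frame(window = nm, t_from = w[1], t_to = w[2],
               mean = mean(vals), sem = stats::sd(vals) / sqrt(length(vals)),
               n = length(vals))
  }))
  structure(list(series = data.frame(t_min = slopes$t_min,
                                     normalized = normalized),
                 window_means = wm,
                 baseline_ok = abs(drift) <= stability_tol,
                 baseline_drift = unname(drift),
                 epochs = list(baseline = baseline_epoch, windows = windows)),
            class = "plasticity_timecourse")
}

#' @export
print.plasticity_timecourse <- function(x, ...) {
  cat("<plasticity_timecourse>\n")
  print(x$window_means, row.names = FALSE)
  if (!x$baseline_ok)
    cat(sprintf("  ! unstable baseline (drift %.2f %%/10 min)\n",
                x$baseline_drift))
  invisible(x)
}

#' Fiber-volley trajectory
#'
#' Normalizes a fiber-volley amplitude series to its baseline mean and
#' summarizes the configured windows (by default the last 5 min of a 15-min
#' LFS and the 35-40 min post-LFS window). Sweeps whose FV is at or below
#' the noise floor are excluded and counted.
#'
#' @param x A \code{data.frame} with columns \code{t_min} and \code{fv_amp}
#'   (mV), or a list of \code{field_sweep}s with \code{meta$t_min} set.
#' @param protocol Induction \code{protocol_spec} (pp_lfs/sp_lfs; sets the
#'   LFS epoch from its duration).
#' @param windows Named list of report windows (min).
#' @param baseline_epoch Baseline window (min).
#' @param config A \code{\link{field_config}} (noise floor; sweep input).
#' @return List of class \code{"fv_trajectory"}: \code{series},
#'   \code{window_means}, \code{n_excluded}.
#' @export
fv_trajectory <- function(x, protocol = NULL, windows = NULL,
                          baseline_epoch = c(-10, 0),
                          config = field_config()) {
  if (!is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(sw) {
      m <- measure_sweep(sw, config)
      data.frame(t_min = sw$meta$t_min, fv_amp = m$fv_amp[1])
    }))
  }
  stopifnot(all(c("t_min", "fv_amp") %in% names(x)))
  flagged <- !is.finite(x$fv_amp) | x$fv_amp <= config$noise_floor
  n_excluded <- sum(flagged)
  x <- x[!flagged, ]
  if (nrow(x) == 0) stop("all sweeps flagged: no measurable fiber volley")
  if (is.null(windows)) {
    lfs_end <- if (!is.null(protocol) && !is.null(protocol$params$duration))
      protocol$params$duration / 60 else 15
    windows <- list(lfs_last5 = c(lfs_end - 5, lfs_end),
                    post_lfs = c(35, 40))
  }
  base_sel <- x$t_min >= baseline_epoch[1] & x$t_min <= baseline_epoch[2]
  if (!any(base_sel)) stop("no samples in the baseline epoch")
  normalized <- 100 * x$fv_amp / mean(x$fv_amp[base_sel])
  wm <- do.call(rbind, lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    sel <- x$t_min >= w[1] & x$t_min <= w[2]
    vals <- normalized[sel]
    data.frame(window = nm, t_from = w[1], t_to = w[2],
               mean = mean(vals), sem = stats::sd(vals) / sqrt(length(vals)),
               n = length(vals))
  }))
  structure(list(series = data.frame(t_min = x$t_min, normalized = normalized),
                 window_means = wm, n_excluded = n_excluded),
            class = "fv_trajectory")
}
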