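#' Episodic voltage trace
#'
#' Container for one uniformly sampled current-clamp sweep. Canonical internal
#' units are mV for voltage, pA for injected current and seconds for time;
#' sample \code{k} (0-based) lives at \code{t0 + k * dt}.
#'
#' @param v Numeric vector of membrane-potential samples (mV).
#' @param dt Sampling interval in seconds (e.g. \code{5e-5} for 20 kHz).
#' @param t0 Time of the first sample in seconds.
#' @param i_cmd Optional injected-current samples (pA), same length as \code{v}.
#' @param meta Named list of provenance (cell id, region label, genotype, ...).
#' @return An object of class \code{"trace"}.
#' @export
voltage_trace <- function(v, dt, t0 = 0, i_cmd = NULL, meta = list()) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds)")
  v <- as.numeric(v)
  if (!all(is.finite(v))) stop("voltage samples must be finite")
  if (!is.null(i_cmd)) {
    i_cmd <- as.numeric(i_cmd)
    if (length(i_cmd) != length(v))
      stop("i_cmd must have the same length as v")
  }
  structure(list(v = v, dt = dt, t0 = t0, i_cmd = i_cmd, meta = meta),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %.6g kHz, %.3f s, V in [%.1f, %.1f] mV\n",
              length(x$v), 1e-3 / x$dt, length(x$v) * x$dt,
              min(x$v), max(x$v)))
  if (!is.null(x$i_cmd))
    cat(sprintf("  i_cmd in [%.1f, %.1f] pA\n", min(x$i_cmd), max(x$i_cmd)))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of a trace or field sweep
#' @param x A \code{trace} or \code{field_sweep}.
#' @return Numeric vector of sample times (s).
#' @export
trace_times <- function(x) {
  t0 <- if (is.null(x$t0)) 0 else x$t0
  t0 + (seq_along(x$v) - 1L) * x$dt
}

#' Extracellular field-potential sweep
#'
#' One stimulus-locked (or continuous multi-stimulus) extracellular sweep.
#'
#' @param v Field-potential samples (mV).
#' @param dt Sampling interval (s).
#' @param stim_times Stimulus onset times (s, strictly increasing, within span).
#'   Onset refers to the start of the stimulus artifact.
#' @param stim_intensity Stimulation intensity (uA), optional scalar.
#' @param landmarks Optional per-stimulus list of ground-truth landmark times
#'   (\code{artifact_window}, \code{fv_trough}, \code{fpsp_peak}).
#' @param t0 Time of first sample (s).
#' @param meta Named provenance list.
#' @return An object of class \code{"field_sweep"}.
#' @export
field_sweep <- function(v, dt, stim_times, stim_intensity = NA_real_,
                        landmarks = NULL, t0 = 0, meta = list()) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number (seconds)")
  v <- as.numeric(v)
  stim_times <- as.numeric(stim_times)
  if (length(stim_times) == 0L) stop("at least one stimulus time required")
  if (any(diff(stim_times) <= 0)) stop("stim_times must be strictly increasing")
  span <- c(t0, t0 + length(v) * dt)
  if (any(stim_times < span[1] | stim_times > span[2]))
    stop("stim_times must lie within the sweep span")
  structure(list(v = v, dt = dt, t0 = t0, stim_times = stim_times,
                 stim_intensity = stim_intensity, landmarks = landmarks,
                 meta = meta),
            class = "field_sweep")
}

#' @export
print.field_sweep <- function(x, ...) {
  cat(sprintf("<field_sweep> %d samples @ %.6g kHz, %d stimuli, %.3f s\n",
              length(x$v), 1e-3 / x$dt, length(x$stim_times),
              length(x$v) * x$dt))
  invisible(x)
}

# required protocol parameters per kind
.protocol_required <- list(
  ramp          = c("i_start", "i_end", "duration"),
  step          = c("amplitude", "duration"),
  membrane_test = c("amplitude", "duration"),
  io_curve      = c("intensities"),
  paired_pulse  = c("isi"),
  train         = c("frequency", "n_pulses"),
  hfs           = c("frequency", "duration", "n_trains", "inter_train"),
  depotentiation = c("frequency", "duration", "delay_after_hfs"),
  pp_lfs        = c("frequency", "duration", "pair_isi"),
  sp_lfs        = c("frequency", "duration"),
  baseline      = c("duration")
)

#' Stimulation / acquisition protocol descriptor
#'
#' Validated descriptor for the protocols used across the pipeline. Parameter
#' units: currents pA, durations s, frequencies Hz, inter-stimulus intervals ms.
#'
#' Kinds and required params:
#' \itemize{
#'   \item \code{ramp}: \code{i_start}, \code{i_end} (pA), \code{duration} (s)
#'     -- e.g. the standard depolarizing ramp 0 to 100 pA in 2 s.
#'   \item \code{step}/\code{membrane_test}: \code{amplitude} (pA),
#'     \code{duration} (s).
#'   \item \code{io_curve}: \code{intensities} (uA vector).
#'   \item \code{paired_pulse}: \code{isi} (ms).
#'   \item \code{train}: \code{frequency} (Hz), \code{n_pulses}.
#'   \item \code{hfs}: \code{frequency}, \code{duration}, \code{n_trains},
#'     \code{inter_train} (s) -- 100 Hz x 1 s, twice, 20 s apart.
#'   \item \code{depotentiation}: \code{frequency}, \code{duration},
#'     \code{delay_after_hfs} (s) -- 5 Hz for 3 min, 5 min after HFS.
#'   \item \code{pp_lfs}: \code{frequency}, \code{duration}, \code{pair_isi}
#'     (ms) -- 1 Hz for 15 min, paired stimuli 50 ms apart.
#'   \item \code{sp_lfs}: \code{frequency}, \code{duration}.
#'   \item \code{baseline}: \code{duration} (s); 0.1 Hz pacing is implied for
#'     field baselines.
#' }
#'
#' @param kind Protocol kind (see above).
#' @param ... Named protocol parameters.
#' @return An object of class \code{"protocol_spec"}.
#' @export
protocol_spec <- function(kind, ...) {
  kind <- match.arg(kind, names(.protocol_required))
  params <- list(...)
  req <- .protocol_required[[kind]]
  missing <- setdiff(req, names(params))
  if (length(missing))
    stop(sprintf("protocol '%s' missing required parameter(s): %s",
                 kind, paste(missing, collapse = ", ")))
  num <- params[vapply(params, is.numeric, logical(1))]
  for (nm in intersect(names(num), c("frequency", "duration", "isi",
                                     "pair_isi", "inter_train"))) {
    if (any(num[[nm]] <= 0))
      stop(sprintf("protocol parameter '%s' must be positive", nm))
  }
  structure(list(kind = kind, params = params), class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  p <- vapply(x$params, function(z) paste(format(z), collapse = ","),
              character(1))
  cat(sprintf("<protocol:%s> %s\n", x$kind,
              paste(names(p), p, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Correct a trace for the liquid junction potential
#'
#' Shifts all voltage samples by \code{-offset_mV} and records the correction
#' in the trace metadata. Applying offsets \code{+x} then \code{-x} restores
#' the original samples.
#'
#' @param trace A \code{trace}.
#' @param offset_mV Junction potential in mV (finite scalar).
#' @return The corrected \code{trace}.
#' @export
liquid_junction_correct <- function(trace, offset_mV) {
  stopifnot(inherits(trace, "trace"))
  if (!is.finite(offset_mV)) stop("offset must be finite")
  trace$v <- trace$v - offset_mV
  prev <- trace$meta$ljp_correction_mV
  trace$meta$ljp_correction_mV <- if (is.null(prev)) offset_mV else prev + offset_mV
  trace
}

#' Result table container
#'
#' Long-format container for per-unit measurements: one row per
#' (unit, measure) with value, units and group label. Duplicate
#' (unit, measure) keys are rejected.
#'
#' @param unit Unit (cell / slice / sample) identifiers.
#' @param measure Measure names.
#' @param value Numeric values.
#' @param units Unit strings, one per row (recycled if scalar).
#' @param group Group labels (recycled if scalar).
#' @return A \code{data.frame} of class \code{"result_table"}.
#' @export
result_table <- function(unit = character(), measure = character(),
                         value = numeric(), units = character(),
                         group = character()) {
  n <- length(value)
  df <- data.frame(unit = as.character(unit),
                   measure = as.character(measure),
                   value = as.numeric(value),
                   units = as.character(rep_len(units, n)),
                   group = as.character(rep_len(group, n)),
                   stringsAsFactors = FALSE)
  key <- paste(df$unit, df$measure, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (unit, measure) keys in result table")
  class(df) <- c("result_table", "data.frame")
  df
}

#' Bind result tables
#' @param ... \code{result_table}s.
#' @return A combined \code{result_table}.
#' @export
bind_results <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  result_table(df$unit, df$measure, df$value, df$units, df$group)
}
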