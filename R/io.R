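# Delimited-sweep dialect: a CSV/TSV with one time column (or a declared dt)
# plus one or more signal columns, and a JSON sidecar describing sampling,
# units, channel roles and the protocol. This is the package's native on-disk
# format; vendor binaries are reached only through user-supplied adapters.

.unit_scale <- list(
  time    = c(s = 1, ms = 1e-3),
  voltage = c(mV = 1, V = 1000, uV = 1e-3),
  current = c(pA = 1, nA = 1000)
)

.to_internal <- function(x, unit, role) {
  sc <- .unit_scale[[role]]
  if (is.null(unit) || !nzchar(unit)) return(x)
  if (!unit %in% names(sc))
    stop(sprintf("unsupported %s unit '%s'", role, unit))
  x * sc[[unit]]
}

#' Read episodic sweeps from a delimited file with JSON sidecar
#'
#' The sidecar declares the sampling (either \code{dt_s} or a time column),
#' channel roles and units, the protocol, and -- for field sweeps -- stimulus
#' times. All signals are converted to internal units (mV, pA, s) on ingest.
#'
#' Sidecar fields: \code{type} ("trace" or "field_sweep"), \code{dt_s},
#' \code{channels} (list of \code{{column, role, units}} with roles
#' \code{time}/\code{voltage}/\code{current}), \code{protocol}
#' (\code{{kind, params}}), \code{stim_times_s}, \code{stim_intensity_uA},
#' \code{meta}.
#'
#' Files whose time stamps deviate from uniform sampling by more than 1% of
#' the sampling interval are rejected.
#'
#' @param path Delimited numeric file (comma or tab separated; header row).
#' @param sidecar Path to the JSON sidecar.
#' @return A list of \code{trace} or \code{field_sweep} objects (one per
#'   voltage channel), each carrying its \code{protocol_spec} in
#'   \code{meta$protocol}.
#' @export
read_sweeps <- function(path, sidecar) {
  if (!file.exists(path)) stop("sweep file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- tryCatch(utils::read.table(path, header = TRUE, sep = sep),
                 error = function(e) stop("format error: ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("format error: empty sweep file")

  ch <- sc$channels
  if (is.null(ch)) stop("format error: sidecar lacks 'channels'")
  ch <- as.data.frame(ch, stringsAsFactors = FALSE)
  if (!all(c("column", "role") %in% names(ch)))
    stop("format error: each channel needs 'column' and 'role'")

  tcol <- ch$column[ch$role == "time"]
  if (length(tcol)) {
    tunits <- ch$units[ch$role == "time"]
    tt <- .to_internal(df[[tcol[1]]], tunits[1], "time")
    if (length(tt) < 2L) stop("format error: need >= 2 samples")
    dts <- diff(tt)
    dt <- stats::median(dts)
    if (dt <= 0 || any(abs(dts - dt) > 0.01 * dt))
      stop("format error: non-uniform sampling beyond tolerance")
    t0 <- tt[1]
  } else if (!is.null(sc$dt_s)) {
    dt <- as.numeric(sc$dt_s)
    t0 <- if (is.null(sc$t0_s)) 0 else as.numeric(sc$t0_s)
  } else {
    stop("format error: sidecar declares neither dt_s nor a time column")
  }

  proto <- NULL
  if (!is.null(sc$protocol))
    proto <- do.call(protocol_spec,
                     c(list(kind = sc$protocol$kind), as.list(sc$protocol$params)))
  meta <- if (is.null(sc$meta)) list() else as.list(sc$meta)
  meta$protocol <- proto

  icol <- ch$column[ch$role == "current"]
  i_cmd <- if (length(icol))
    .to_internal(df[[icol[1]]], ch$units[ch$role == "current"][1], "current")

  vrows <- which(ch$role == "voltage")
  if (!length(vrows)) stop("format error: no voltage channel declared")
  type <- if (is.null(sc$type)) "trace" else sc$type
  lapply(vrows, function(k) {
    v <- .to_internal(df[[ch$column[k]]], ch$units[k], "voltage")
    if (identical(type, "field_sweep")) {
      field_sweep(v, dt = dt, t0 = t0,
                  stim_times = as.numeric(sc$stim_times_s),
                  stim_intensity = if (is.null(sc$stim_intensity_uA))
                    NA_real_ else as.numeric(sc$stim_intensity_uA),
                  meta = meta)
    } else {
      voltage_trace(v, dt = dt, t0 = t0, i_cmd = i_cmd, meta = meta)
    }
  })
}

#' Write a sweep in the delimited + sidecar dialect
#'
#' Inverse of \code{\link{read_sweeps}} for a single sweep; emits a CSV with a
#' time column plus signal column(s) and the JSON sidecar.
#'
#' @param sweep A \code{trace} or \code{field_sweep}.
#' @param path Output CSV path; the sidecar is written to \code{<path>.json}.
#' @return Invisibly, the sidecar path.
#' @export
write_sweep <- function(sweep, path) {
  df <- data.frame(t = trace_times(sweep), v = sweep$v)
  sc <- list(dt_s = sweep$dt, t0_s = sweep$t0,
             channels = data.frame(column = c("t", "v"),
                                   role = c("time", "voltage"),
                                   units = c("s", "mV")))
  if (inherits(sweep, "field_sweep")) {
    sc$type <- "field_sweep"
    sc$stim_times_s <- sweep$stim_times
    if (is.finite(sweep$stim_intensity)) sc$stim_intensity_uA <- sweep$stim_intensity
  } else {
    sc$type <- "trace"
    if (!is.null(sweep$i_cmd)) {
      df$i <- sweep$i_cmd
      sc$channels <- rbind(sc$channels,
                           data.frame(column = "i", role = "current", units = "pA"))
    }
  }
  proto <- sweep$meta$protocol
  if (!is.null(proto)) sc$protocol <- list(kind = proto$kind, params = proto$params)
  meta <- sweep$meta; meta$protocol <- NULL
  if (length(meta)) sc$meta <- meta
  utils::write.csv(df, path, row.names = FALSE)
  side <- paste0(path, ".json")
  jsonlite::write_json(sc, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}

#' Write a result table to CSV
#'
#' Serializes with full double precision so that \code{\link{read_results}}
#' reproduces finite values bit-exactly; \code{NaN}/\code{NA} values are
#' written as empty cells and come back as \code{NA}.
#'
#' @param table A \code{result_table}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_results <- function(table, path) {
  stopifnot(inherits(table, "result_table"))
  df <- as.data.frame(table)
  df$value <- vapply(df$value, function(x)
    if (is.finite(x)) sprintf("%.17g", x) else "", character(1))
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       qmethod = "double", quote = c(1L, 2L, 4L, 5L))
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}

#' Read a result table written by \code{write_results}
#' @param path CSV path.
#' @return A \code{result_table}.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, colClasses = c(value = "numeric"),
                        stringsAsFactors = FALSE)
  df$units[is.na(df$units)] <- ""
  df$group[is.na(df$group)] <- ""
  result_table(df$unit, df$measure, df$value, df$units, df$group)
}
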