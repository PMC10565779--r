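#' Parameters of the dynamic-synapse model
#'
#' Tsodyks-Markram short-term plasticity parameters for the synthetic
#' Schaffer-collateral synapse driving the field-sweep generator.
#'
#' @param U Baseline release fraction, in (0, 1].
#' @param tau_f Facilitation decay time constant (ms).
#' @param tau_d Recovery from depression time constant (ms).
#' @param A Absolute first-pulse response scale (mV, fPSP peak for relative
#'   amplitude 1).
#' @return An object of class \code{"stp_params"}.
#' @export
stp_params <- function(U = 0.2, tau_f = 200, tau_d = 500, A = 1.5) {
  stopifnot(U > 0, U <= 1, tau_f > 0, tau_d > 0, A > 0)
  structure(list(U = U, tau_f = tau_f, tau_d = tau_d, A = A),
            class = "stp_params")
}

#' Deterministic short-term plasticity recurrence
#'
#' Per-pulse relative response amplitudes of the facilitation/depression
#' state model for a regular train. State-update order at each pulse, fixed
#' by convention: read the response \code{u_n * R_n}; facilitate
#' \code{u <- u + U * (1 - u)}; deplete \code{R <- R - u_n * R_n} (the
#' released fraction); then relax \code{u -> U} with \code{tau_f} and
#' \code{R -> 1} with \code{tau_d} over the inter-stimulus interval.
#' Initial state \code{u_1 = U}, \code{R_1 = 1}; responses are normalized so
#' the first pulse equals 1.
#'
#' @param params An \code{\link{stp_params}} record.
#' @param frequency Stimulation frequency (Hz); ignored if \code{isi_ms} given.
#' @param n_pulses Number of pulses (>= 1).
#' @param isi_ms Optional explicit inter-stimulus interval (ms) overriding
#'   \code{frequency}.
#' @return Numeric vector of \code{n_pulses} relative amplitudes, first = 1.
#' @export
simulate_stp_train <- function(params, frequency, n_pulses, isi_ms = NULL) {
  stopifnot(inherits(params, "stp_params"), n_pulses >= 1)
  if (is.null(isi_ms)) {
    stopifnot(frequency > 0)
    isi_ms <- 1000 / frequency
  }
  U <- params$U
  u <- U; R <- 1
  resp <- numeric(n_pulses)
  for (n in seq_len(n_pulses)) {
    rel <- u * R
    resp[n] <- rel
    if (n == n_pulses) break
    u <- u + U * (1 - u)
    R <- R - rel
    decay_f <- exp(-isi_ms / params$tau_f)
    decay_d <- exp(-isi_ms / params$tau_d)
    u <- U + (u - U) * decay_f
    R <- 1 - (1 - R) * decay_d
  }
  resp / resp[1]
}
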