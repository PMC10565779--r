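#' Parameters of the model neuron
#'
#' Parameter record for the adaptive exponential integrate-and-fire (AdEx)
#' forward model used as the synthetic stand-in for a CA1 pyramidal cell.
#' Defaults emulate a dorsal-like pyramidal neuron: resting potential near
#' -76 mV, input resistance 200 MOhm, capacitance 80 pF, firing on the
#' standard 0-100 pA / 2 s ramp with a rheobase near 80-90 pA and
#' spike-frequency adaptation from the spike-triggered adaptation current.
#'
#' @param E_L Leak reversal / resting potential (mV).
#' @param R Input resistance (MOhm).
#' @param C Membrane capacitance (pF); the membrane time constant is R*C.
#' @param V_T Spike-initiation threshold of the exponential term (mV).
#' @param Delta_T Slope factor (mV); small values approach the hard-threshold
#'   leaky integrate-and-fire limit.
#' @param V_reset Post-spike reset potential (mV).
#' @param V_peak Spike cutoff (mV); crossing it registers a spike.
#' @param tau_w Adaptation time constant (ms).
#' @param a Subthreshold adaptation conductance (nS).
#' @param b Spike-triggered adaptation increment (pA).
#' @param noise_sd SD of additive Gaussian observation noise on the recorded
#'   voltage (mV); 0 gives a deterministic trace.
#' @return An object of class \code{"neuron_params"}.
#' @export
neuron_params <- function(E_L = -76, R = 200, C = 80, V_T = -58,
                          Delta_T = 2, V_reset = -58, V_peak = 30,
                          tau_w = 150, a = 0, b = 20, noise_sd = 0) {
  stopifnot(R > 0, C > 0, Delta_T > 0, tau_w > 0, V_reset < V_peak,
            noise_sd >= 0)
  structure(list(E_L = E_L, R = R, C = C, V_T = V_T, Delta_T = Delta_T,
                 V_reset = V_reset, V_peak = V_peak, tau_w = tau_w,
                 a = a, b = b, noise_sd = noise_sd),
            class = "neuron_params")
}

# Build the injected-current vector (pA) for a protocol, with quiet padding
# before and after the stimulus. Returns the current and the stimulus epoch.
.protocol_current <- function(protocol, dt_s, pre_s, post_s) {
  p <- protocol$params
  stim <- switch(protocol$kind,
    ramp = {
      n <- round(p$duration / dt_s)
      seq(p$i_start, p$i_end, length.out = n)
    },
    step = rep(p$amplitude, round(p$duration / dt_s)),
    membrane_test = {
      half <- round(p$duration / (2 * dt_s))
      c(rep(p$amplitude, half), rep(-p$amplitude, half))
    },
    baseline = rep(0, round(p$duration / dt_s)),
    stop("unsupported protocol kind for simulation: ", protocol$kind)
  )
  npre <- round(pre_s / dt_s); npost <- round(post_s / dt_s)
  list(i = c(rep(0, npre), stim, rep(0, npost)),
       onset = npre * dt_s, end = (npre + length(stim)) * dt_s)
}

#' Simulate a current-clamp recording from the model neuron
#'
#' Forward-Euler AdEx integration at the requested sampling interval
#' (default 0.05 ms, i.e. 20 kHz). The protocol current is preceded and
#' followed by quiet padding so downstream analyses have a baseline window.
#' Observation noise is added to the integrated voltage; identical seed and
#' inputs give an identical trace.
#'
#' @param params A \code{\link{neuron_params}} record.
#' @param protocol A \code{\link{protocol_spec}} of kind \code{ramp},
#'   \code{step}, \code{membrane_test} or \code{baseline}.
#' @param seed Integer seed for the observation noise.
#' @param dt Sampling interval (s).
#' @param pre_s,post_s Quiet padding before/after the stimulus (s).
#' @return A \code{trace} with \code{i_cmd} populated and
#'   \code{meta$stim_onset}/\code{meta$stim_end} (s) marking the stimulus
#'   epoch; \code{meta$spike_idx} holds the integrator's own spike samples.
#' @export
simulate_neuron <- function(params, protocol, seed = 1L, dt = 5e-5,
                            pre_s = 0.5, post_s = 0.2) {
  stopifnot(inherits(params, "neuron_params"), inherits(protocol, "protocol_spec"))
  cur <- .protocol_current(protocol, dt, pre_s, post_s)
  out <- .adex_integrate(cur$i, dt * 1000, params$E_L, params$R, params$C,
                         params$V_T, params$Delta_T, params$V_reset,
                         params$V_peak, params$tau_w, params$a, params$b,
                         v0 = params$E_L)
  v <- out$v
  if (params$noise_sd > 0)
    v <- v + with_seed(seed, rnorm(length(v), 0, params$noise_sd))
  voltage_trace(v, dt = dt, i_cmd = cur$i,
        meta = list(protocol = protocol, stim_onset = cur$onset,
                    stim_end = cur$end, spike_idx = out$spike_idx,
                    model = "adex"))
}

#' Quasi-static rheobase of the model neuron
#'
#' For a slow ramp the membrane tracks its steady state, so the first spike
#' occurs when the injected current reaches \code{(V_T - E_L)/R} (the leaky
#' integrate-and-fire limit, exact as \code{Delta_T} and the ramp speed go to
#' zero; the exponential term and finite ramp speed shift it slightly).
#'
#' @param params A \code{\link{neuron_params}} record.
#' @return Rheobase estimate in pA.
#' @export
quasistatic_rheobase <- function(params) {
  1000 * (params$V_T - params$E_L) / params$R
}
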