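# Shared synthetic fixtures, built in code at test time.

# ---- constructed AP family -------------------------------------------------
# Phase-plane velocity field g(V) = dV/dt with a slow leak creep, a sharp
# initiation kink at Vth (the analytic threshold: argmax of dg/dV) and a
# broad later acceleration. Integrated with RK4 and sampled like a recording.
g_of_v <- function(V, Vth, w1 = 1, g1 = 15, g2 = 125, V2 = Vth + 20,
                   w2 = 12, g0 = 0.5) {
  g0 + g1 * stats::plogis((V - Vth) / w1) +
    g2 * stats::plogis((V - V2) / w2)
}

build_ap <- function(Vth, w1 = 1, g1 = 15, g2 = 125, V2 = Vth + 20,
                     w2 = 12, g0 = 0.5, Vstart = -70, Vpeak = 10,
                     dt_ms = 0.05, refine = 1) {
  dt <- dt_ms / refine
  f <- function(V) g_of_v(V, Vth, w1, g1, g2, V2, w2, g0)
  v <- Vstart
  out <- numeric(0)
  while (v < Vpeak && length(out) < 2e5) {
    out <- c(out, v)
    k1 <- f(v); k2 <- f(v + dt / 2 * k1)
    k3 <- f(v + dt / 2 * k2); k4 <- f(v + dt * k3)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  n <- length(out)
  dec <- seq(out[n], -65, by = -2.5 * dt)[-1]
  voltage_trace(c(out, dec), dt = dt / 1000, meta = list(peak_idx = n))
}

# analytic threshold of the family: argmax of dg/dV on a very dense grid
analytic_threshold <- function(Vth, ...) {
  vs <- seq(-70, 0, by = 0.001)
  g <- g_of_v(vs, Vth, ...)
  vs[which.max(diff(g) / diff(vs))]
}

# ---- independent STP oracle ------------------------------------------------
# Hand-stepped facilitation/depression recurrence, written independently of
# simulate_stp_train: per-pulse loop over scalar state with explicit decays.
stp_oracle <- function(U, tau_f, tau_d, isi_ms, n) {
  u <- U; r <- 1
  rel <- numeric(n)
  for (k in seq_len(n)) {
    rel[k] <- u * r
    u_after <- u + U * (1 - u)
    r_after <- r * (1 - u)
    u <- U + (u_after - U) * exp(-isi_ms / tau_f)
    r <- 1 - (1 - r_after) * exp(-isi_ms / tau_d)
  }
  rel / rel[1]
}

# ---- misc ------------------------------------------------------------------
# render a current-clamp trace with idealized triangular APs at given peak
# times; baseline flat. rise/fall in ms, amplitudes in mV above baseline.
render_triangle_spikes <- function(peak_times_s, baseline = -70, peak = 40,
                                   rise_ms = 0.5, fall_ms = 0.5,
                                   duration_s = NULL, dt = 5e-5) {
  if (is.null(duration_s)) duration_s <- max(peak_times_s) + 0.05
  n <- round(duration_s / dt)
  tt <- (seq_len(n) - 1) * dt
  v <- rep(baseline, n)
  for (pk in peak_times_s) {
    up <- tt >= pk - rise_ms / 1000 & tt <= pk
    v[up] <- baseline + (peak - baseline) *
      (1 - (pk - tt[up]) / (rise_ms / 1000))
    dn <- tt > pk & tt <= pk + fall_ms / 1000
    v[dn] <- baseline + (peak - baseline) * (1 - (tt[dn] - pk) / (fall_ms / 1000))
  }
  voltage_trace(v, dt = dt)
}
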