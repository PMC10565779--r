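test_that("RMP is the baseline mean, and contaminated or misplaced windows error", {
  tr <- voltage_trace(rep(-76, 20000), dt = 5e-5,
                      meta = list(stim_onset = 0.8))
  expect_equal(measure_rmp(tr), -76)
  # noisy baseline recovers the mean within sampling error
  set.seed(21)
  trn <- voltage_trace(-70 + rnorm(10000, 0, 0.5), dt = 5e-5,
                       meta = list(stim_onset = 0.5))
  expect_equal(measure_rmp(trn), -70, tolerance = 0.05)
  # window must be >= 100 ms and precede the stimulus
  expect_error(measure_rmp(tr, window = c(0, 0.05)), "100 ms")
  expect_error(measure_rmp(tr, window = c(0.5, 0.9)), "overlaps")
  # spikes in the window are a contaminated baseline
  spiky <- render_triangle_spikes(c(0.2, 0.3), duration_s = 0.6)
  spiky$meta$stim_onset <- 0.6
  expect_error(measure_rmp(spiky), "contaminated")
})

test_that("junction correction configured in the analysis shifts the RMP", {
  tr <- voltage_trace(rep(-66, 20000), dt = 5e-5,
                      meta = list(stim_onset = 0.8))
  cfg <- intrinsic_config(junction_offset_mV = 10)
  expect_equal(measure_rmp(tr, config = cfg), -76)
})

test_that("spike detection finds rendered APs and enforces the refractory period", {
  expect_identical(
    detect_spikes(voltage_trace(rep(-70, 4000), dt = 5e-5))$times,
    numeric(0))
  peaks <- c(0.1, 0.15, 0.22, 0.3, 0.41)
  tr <- render_triangle_spikes(peaks)
  det <- detect_spikes(tr)
  expect_length(det$times, 5)
  expect_equal(det$peak_times, peaks, tolerance = 1e-4)
  # two smooth upstrokes 1.2 ms apart collapse to one detection at the
  # default 2 ms refractory but are both seen at 0.5 ms
  tt <- (seq_len(4000) - 1) * 5e-5
  v2 <- -70 + 110 * exp(-(tt - 0.1)^2 / (2 * 2e-4^2)) +
        110 * exp(-(tt - 0.1012)^2 / (2 * 2e-4^2))
  tr2 <- voltage_trace(v2, 5e-5)
  expect_length(detect_spikes(tr2)$times, 1)
  expect_length(detect_spikes(tr2, intrinsic_config(refractory_ms = 0.5))$times, 2)
  # sampling coarser than 0.1 ms is refused
  expect_error(detect_spikes(voltage_trace(rep(-70, 100), dt = 2e-4)),
               "0.1 ms")
})

test_that("phase-plane threshold recovers the constructed kink and rejects degenerate input", {
  seg <- build_ap(Vth = -52)
  expect_equal(as.numeric(ap_threshold(seg)),
               analytic_threshold(Vth = -52), tolerance = 0.6)
  # a linear voltage ramp has constant dV/dt: threshold undefined
  ramp <- voltage_trace(seq(-70, 0, length.out = 400), dt = 5e-5)
  expect_error(ap_threshold(ramp), "threshold undefined")
})

test_that("threshold operator matches its 10x-refined oracle on the AP family", {
  # the oracle refines the sampling 10x and keeps the smoothing timescale
  # (0.35 ms) and the phase-plane grid dense
  cfg_fine <- intrinsic_config(sg_window = 71)
  for (Vth in c(-55, -51, -48)) {
    coarse <- as.numeric(ap_threshold(build_ap(Vth)))
    fine <- as.numeric(ap_threshold(build_ap(Vth, refine = 10), cfg_fine,
                                    grid_mV = 0.01))
    expect_lt(abs(coarse - fine), 1, label = paste("Vth", Vth))
    expect_lt(abs(coarse - analytic_threshold(Vth)), 2,
              label = paste("Vth", Vth, "analytic"))
  }
})

test_that("AdEx spike thresholds land between V_T and the spike cutoff region", {
  tr <- simulate_neuron(neuron_params(E_L = -70, V_T = -50),
                        protocol_spec("ramp", i_start = 0, i_end = 100,
                                      duration = 2))
  seg <- detect_spikes(tr)$segments[[1]]
  thr <- as.numeric(ap_threshold(seg))
  expect_gt(thr, -50)
  expect_lt(thr, -35)
})

test_that("AP features follow the waveform geometry", {
  # symmetric triangular AP: threshold -50, peak +50 -> amplitude 100,
  # half-width 1 ms for a 1 ms rise / 1 ms fall
  tr <- render_triangle_spikes(0.05, baseline = -50, peak = 50,
                               rise_ms = 1, fall_ms = 1, duration_s = 0.1)
  seg <- detect_spikes(tr)$segments[[1]]
  ft <- ap_features(seg, threshold = -50)
  expect_equal(ft$amplitude, 100, tolerance = 1e-6)
  expect_equal(ft$half_width, 1, tolerance = 0.01)
  expect_true(is.na(ft$fahp_amp)) # no post-peak minimum below threshold

  # known maximal rise slope: 100 mV over 0.25 ms = 400 mV/ms
  tr2 <- render_triangle_spikes(0.05, baseline = -50, peak = 50,
                                rise_ms = 0.25, fall_ms = 1,
                                duration_s = 0.1)
  seg2 <- detect_spikes(tr2)$segments[[1]]
  ft2 <- ap_features(seg2, threshold = -50)
  expect_equal(ft2$max_rise_slope, 400, tolerance = 2 / 400)

  # constructed after-potential: minimum 7.5 mV below threshold, 2.4 ms
  # after the peak
  dt <- 5e-5
  n <- 2000
  v <- rep(-55, n)
  pk <- 500
  v[(pk - 20):pk] <- seq(-55, 40, length.out = 21)
  v[(pk + 1):(pk + 48)] <- seq(40, -57.5, length.out = 48)
  v[(pk + 48):(pk + 120)] <- seq(-57.5, -55, length.out = 73)
  seg3 <- voltage_trace(v, dt, meta = list(peak_idx = pk))
  ft3 <- ap_features(seg3, threshold = -50)
  expect_equal(ft3$fahp_amp, 7.5, tolerance = 1e-6)
  expect_equal(ft3$fahp_delay, 2.4, tolerance = 0.1)

  expect_error(ap_features(seg3, threshold = 50), "below the peak")
})

test_that("ramp analysis interpolates rheobase at the threshold-crossing time", {
  # constructed cell: one AP whose upstroke sits at 1.2 s into the
  # 0-100 pA / 2 s ramp -> rheobase 60 pA
  dt <- 5e-5
  n <- round(3 / dt)
  v <- rep(-70, n)
  tt <- (seq_len(n) - 1) * dt
  onset <- 0.5
  spike_t <- onset + 1.2
  # slow depolarization toward threshold, then a fast AP at spike_t
  ramp_sel <- tt >= onset & tt < spike_t
  v[ramp_sel] <- -70 + 12 * (tt[ramp_sel] - onset) / 1.2
  up <- tt >= spike_t & tt < spike_t + 5e-4
  v[up] <- -58 + (tt[up] - spike_t) / 5e-4 * 98
  dn <- tt >= spike_t + 5e-4 & tt < spike_t + 15e-4
  v[dn] <- 40 - (tt[dn] - spike_t - 5e-4) / 1e-3 * 105
  v[tt >= spike_t + 15e-4] <- -65
  tr <- voltage_trace(v, dt, meta = list(stim_onset = onset))
  proto <- protocol_spec("ramp", i_start = 0, i_end = 100, duration = 2)
  rr <- analyze_ramp(tr, proto)
  expect_equal(rr$n_spikes, 1)
  expect_equal(rr$rheobase, 60, tolerance = 1)
  expect_equal(rr$from_potential, -70, tolerance = 1e-6)

  # no spikes: zero count, undefined rheobase
  quiet <- voltage_trace(rep(-70, n), dt, meta = list(stim_onset = onset))
  rq <- analyze_ramp(quiet, proto)
  expect_equal(rq$n_spikes, 0)
  expect_true(is.na(rq$rheobase))

  # missing ramp metadata is a protocol error
  expect_error(analyze_ramp(voltage_trace(rep(-70, 1000), dt)), "protocol")
})

test_that("passive properties recover R, tau and C from a step", {
  p <- neuron_params(E_L = -70, R = 200, C = 80, V_T = 0)
  tr <- simulate_neuron(p, protocol_spec("step", amplitude = -25,
                                         duration = 0.4))
  pp <- passive_from_step(tr)
  expect_equal(pp$r_n, 200, tolerance = 0.005)
  expect_equal(pp$tau_m, 16, tolerance = 0.02)
  expect_equal(pp$c_m, 80, tolerance = 0.03)
  # zero-amplitude step cannot define R_N
  proto0 <- protocol_spec("step", amplitude = 0, duration = 0.4)
  tr0 <- simulate_neuron(p, proto0)
  expect_error(passive_from_step(tr0, proto0), "undefined r_n")
})

test_that("ramp measures are invariant to shifting the time axis", {
  p <- neuron_params(E_L = -70, R = 200, C = 80, V_T = -50)
  proto <- protocol_spec("ramp", i_start = 0, i_end = 100, duration = 2)
  tr <- simulate_neuron(p, proto)
  rr1 <- analyze_ramp(tr)
  tr2 <- tr
  tr2$t0 <- 12.5
  tr2$meta$stim_onset <- tr$meta$stim_onset + 12.5
  rr2 <- analyze_ramp(tr2)
  expect_equal(rr2$n_spikes, rr1$n_spikes)
  expect_equal(rr2$rheobase, rr1$rheobase, tolerance = 1e-9)
  expect_equal(rr2$spike_times - 12.5, rr1$spike_times, tolerance = 1e-9)
})

test_that("spike counts rise and rheobase falls with R and with depolarized E_L", {
  proto <- protocol_spec("ramp", i_start = 0, i_end = 100, duration = 2)
  by_R <- lapply(c(150, 200, 250), function(R)
    analyze_ramp(simulate_neuron(neuron_params(R = R), proto)))
  ns <- vapply(by_R, `[[`, numeric(1), "n_spikes")
  rb <- vapply(by_R, `[[`, numeric(1), "rheobase")
  expect_true(all(diff(ns) >= 0))
  expect_true(all(diff(rb[!is.na(rb)]) <= 0))

  by_EL <- lapply(c(-76, -73), function(E)
    analyze_ramp(simulate_neuron(neuron_params(E_L = E), proto)))
  expect_gte(by_EL[[2]]$n_spikes, by_EL[[1]]$n_spikes)
  expect_lte(by_EL[[2]]$rheobase, by_EL[[1]]$rheobase)
})
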