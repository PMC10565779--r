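test_that("a linear rising phase yields its slope irrespective of the 20-80% bounds", {
  # construct a sweep whose fPSP rising phase is exactly linear at 1 mV/ms
  dt <- 5e-5
  n <- 4000
  tt_ms <- (seq_len(n) - 1) * dt * 1000
  v <- numeric(n)
  on <- 50; peak_ms <- 10
  rise <- tt_ms >= on & tt_ms < on + peak_ms
  v[rise] <- -(tt_ms[rise] - on) * 1
  after <- tt_ms >= on + peak_ms
  v[after] <- -peak_ms + (tt_ms[after] - on - peak_ms) * 0.2
  v[after][v[after] > 0] <- 0
  sw <- field_sweep(v, dt, stim_times = (on - 3) / 1000)
  cfg <- field_config(fpsp_window_ms = c(1, 60), fv_window_ms = c(0.2, 0.8),
                      overlap = "none")
  m <- measure_sweep(sw, cfg)
  expect_equal(m$fpsp_slope, 1, tolerance = 1e-9)
  expect_equal(m$fpsp_amp, 10, tolerance = 1e-9)
})

test_that("the 20-80% slope of a kernel fPSP matches a dense-grid oracle within 1%", {
  kin <- field_kinetics(noise_sd = 0, fpsp_amp = 1.5)
  sw <- synthesize_field_sweeps(1, kin, protocol_spec("baseline", duration = 1))
  m <- measure_sweep(sw)
  # oracle: crossings and least-squares slope on the closed-form kernel
  # evaluated on a 1 MHz grid
  t_us <- seq(0, 40, by = 0.001)
  y <- -1.5 * fpsp_kernel(t_us, kin)
  pk <- which.min(y)
  lo <- -0.2 * 1.5; hi <- -0.8 * 1.5
  i20 <- which(y[1:pk] <= lo)[1]
  i80 <- which(y[1:pk] <= hi)[1]
  sel <- i20:i80
  oracle <- abs(stats::lm.fit(cbind(1, t_us[sel]), y[sel])$coefficients[2])
  expect_equal(m$fpsp_slope, unname(oracle), tolerance = 0.01)
})

test_that("slope and amplitude are invariant to vertical offset and time shift", {
  kin <- field_kinetics(noise_sd = 0)
  sw <- synthesize_field_sweeps(1, kin, protocol_spec("baseline", duration = 1))
  m0 <- measure_sweep(sw)
  sw_off <- sw; sw_off$v <- sw$v + 3.7
  m1 <- measure_sweep(sw_off)
  sw_sh <- sw; sw_sh$t0 <- 5; sw_sh$stim_times <- sw$stim_times + 5
  m2 <- measure_sweep(sw_sh)
  expect_equal(m1$fpsp_slope, m0$fpsp_slope, tolerance = 1e-9)
  expect_equal(m1$fpsp_amp, m0$fpsp_amp, tolerance = 1e-9)
  expect_equal(m2$fpsp_slope, m0$fpsp_slope, tolerance = 1e-9)
  expect_equal(m2$fpsp_amp, m0$fpsp_amp, tolerance = 1e-9)
})

test_that("input-output curves invert to the requested fraction of maximum", {
  # sigmoid synthetic I-O relation with analytically known half point
  intens <- seq(10, 100, by = 10)
  amp_of <- function(i) 2 / (1 + exp(-(i - 45) / 10))
  curve <- data.frame(intensity = intens, amplitude = amp_of(intens))
  io <- io_curve(curve)
  a_max <- max(curve$amplitude)
  target <- 0.5 * a_max
  analytic <- 45 - 10 * log(2 / target - 1)
  expect_equal(io$intensity_for_fraction(0.5), analytic, tolerance = 0.02)
  expect_equal(io$intensity_for_fraction(1), 100)
  expect_error(io$intensity_for_fraction(1.5), "unreachable")
  # two-point curve: plain linear interpolation
  io2 <- io_curve(data.frame(intensity = c(10, 20), amplitude = c(1, 2)))
  expect_equal(io2$intensity_for_fraction(0.75), 15)
  # non-monotone beyond tolerance warns
  expect_warning(io_curve(data.frame(intensity = 1:5,
                                     amplitude = c(1, 2, 1.2, 2.5, 3))),
                 "non-monotone")
})

test_that("paired-pulse ratios match the recurrence oracle after rendering", {
  amps <- c(0.5, 1.0) / 1.5
  kin <- field_kinetics(noise_sd = 0)
  sw <- synthesize_field_sweeps(amps, kin, protocol_spec("paired_pulse",
                                                         isi = 200))
  expect_equal(paired_pulse_ratio(sw), 2, tolerance = 1e-3)

  p <- stp_params(U = 0.2, tau_f = 200, tau_d = 500)
  a2 <- simulate_stp_train(p, n_pulses = 2, isi_ms = 50)
  sw2 <- synthesize_field_sweeps(a2, kin, protocol_spec("paired_pulse",
                                                        isi = 50))
  oracle <- stp_oracle(0.2, 200, 500, 50, 2)[2]
  expect_equal(paired_pulse_ratio(sw2), oracle, tolerance = 0.02 * oracle)
  expect_equal(oracle, 1.33, tolerance = 0.005)

  # a first response at the noise floor leaves the ratio undefined
  kin0 <- field_kinetics(noise_sd = 0, fv_amp = 0)
  tiny <- synthesize_field_sweeps(c(0.001, 0.5), kin0,
                                  protocol_spec("paired_pulse", isi = 200))
  expect_error(paired_pulse_ratio(tiny), "noise floor")
})

test_that("the PPR series summary is last-20 mean over the first ratio", {
  expect_equal(ppr_series_summary(c(2, rep(1.5, 20))), 0.75)
})

test_that("train analysis normalizes to the pre-train baseline", {
  flat <- analyze_train(rep(1.2, 100), baseline = 1.2)
  expect_true(all(flat$trajectory == 100))
  expect_equal(flat$last_mean, 100)

  # facilitating render with a known plateau
  p <- stp_params(U = 0.2, tau_f = 200, tau_d = 500)
  amps <- simulate_stp_train(p, frequency = 5, n_pulses = 100)
  kin <- field_kinetics(noise_sd = 0)
  sw <- synthesize_field_sweeps(amps, kin, protocol_spec("train",
                                                         frequency = 5,
                                                         n_pulses = 100))
  m <- measure_sweep(sw)
  res <- analyze_train(m$fpsp_amp, baseline = kin$fpsp_amp)
  truth <- 100 * mean(amps[91:100])
  expect_equal(res$last_mean, truth, tolerance = 0.02 * truth)

  # depressing train ends below baseline
  pd <- stp_params(U = 0.9, tau_f = 50, tau_d = 2000)
  ad <- simulate_stp_train(pd, frequency = 100, n_pulses = 100)
  resd <- analyze_train(ad * 1.0, baseline = 1.0)
  expect_lt(resd$last_mean, 100)
  expect_true(all(diff(resd$trajectory[1:10]) < 0))

  expect_error(analyze_train(rep(1, 100), baseline = NA), "baseline")
})

test_that("tuning curves collect per-frequency summaries and reject duplicates", {
  single <- tuning_curve(list("5" = rep(100, 100)))
  expect_equal(single$max_facilitation, 100)
  expect_equal(single$last_mean, 100)

  # facilitation/depression synapse across the 1-100 Hz protocol grid: the
  # measured curve must match the recurrence oracle pointwise and in argmax
  p <- stp_params(U = 0.2, tau_f = 200, tau_d = 1500)
  freqs <- c(1, 5, 10, 20, 100)
  trains <- lapply(freqs, function(f)
    100 * simulate_stp_train(p, frequency = f, n_pulses = 100))
  names(trains) <- freqs
  tc <- tuning_curve(trains)
  oracle_last10 <- vapply(freqs, function(f)
    mean(stp_oracle(0.2, 200, 1500, 1000 / f, 100)[91:100]), numeric(1))
  expect_equal(tc$last_mean[order(tc$frequency)],
               100 * oracle_last10[order(freqs)], tolerance = 1e-9)
  expect_equal(tc$frequency[which.max(tc$last_mean)],
               freqs[which.max(oracle_last10)])
  # with these parameters transient facilitation grows with frequency while
  # the steady state depresses: max facilitation rises, last-10 mean falls
  expect_true(all(diff(tc$max_facilitation[order(tc$frequency)]) > 0))
  expect_true(all(diff(tc$last_mean[order(tc$frequency)]) < 0))

  expect_error(tuning_curve(list("5" = rep(100, 10), "5" = rep(90, 10))),
               "duplicated")
})

test_that("plasticity quantification reports window means on the % scale", {
  ltp <- simulate_plasticity_timecourse(1.0, 1.9, tau_onset = 5, noise_sd = 0)
  q <- plasticity_quantify(ltp, protocol_spec("hfs", frequency = 100,
                                              duration = 1, n_trains = 2,
                                              inter_train = 20))
  base <- q$series$normalized[q$series$t_min <= 0]
  expect_equal(mean(base), 100, tolerance = 1e-9)
  expect_equal(q$window_means$mean, 190, tolerance = 0.02 * 190)
  expect_true(q$baseline_ok)

  flat <- simulate_plasticity_timecourse(1.0, 1.0, tau_onset = 5)
  qf <- plasticity_quantify(flat, windows = list(w = c(51, 60)))
  expect_equal(qf$window_means$mean, 100, tolerance = 1e-9)

  ltd <- simulate_plasticity_timecourse(1.0, 0.86, tau_onset = 5)
  ql <- plasticity_quantify(ltd, protocol_spec("pp_lfs", frequency = 1,
                                               duration = 900,
                                               pair_isi = 50))
  expect_equal(ql$window_means$mean, 86, tolerance = 0.02 * 86)
  expect_equal(ql$window_means$t_from, 35)
  expect_equal(ql$window_means$t_to, 40)
})

test_that("a drifting baseline trips the stability gate", {
  s <- simulate_plasticity_timecourse(1.0, 1.5, tau_onset = 5)
  s$value[s$t_min <= 0] <- 1 + 0.02 * s$t_min[s$t_min <= 0] # 20%/10 min drift
  q <- plasticity_quantify(s, windows = list(w = c(51, 60)))
  expect_false(q$baseline_ok)
})

test_that("fiber-volley trajectories summarize suppression and recovery", {
  t_min <- seq(-10, 45, by = 1 / 6)
  fv <- ifelse(t_min <= 0, 0.5,
        ifelse(t_min <= 15, 0.5 * 0.33, 0.5 * 0.91))
  flat <- fv_trajectory(data.frame(t_min = t_min, fv_amp = rep(0.5, length(t_min))))
  expect_true(all(abs(flat$series$normalized - 100) < 1e-9))

  tr <- fv_trajectory(data.frame(t_min = t_min, fv_amp = fv),
                      protocol = protocol_spec("pp_lfs", frequency = 1,
                                               duration = 900,
                                               pair_isi = 50))
  wm <- tr$window_means
  expect_equal(wm$mean[wm$window == "lfs_last5"], 33, tolerance = 0.02 * 33)
  expect_equal(wm$mean[wm$window == "post_lfs"], 91, tolerance = 0.02 * 91)
  expect_equal(tr$n_excluded, 0)

  # unmeasurable series: everything flagged
  expect_error(fv_trajectory(data.frame(t_min = 1:5, fv_amp = rep(0.001, 5))),
               "all sweeps flagged")
})
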