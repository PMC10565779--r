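test_that("voltage_trace and field_sweep enforce their invariants", {
  expect_error(voltage_trace(1:3, dt = 0), "positive")
  expect_error(voltage_trace(c(1, NA), dt = 1e-4), "finite")
  expect_error(voltage_trace(1:3, dt = 1e-4, i_cmd = 1:2), "same length")
  tr <- voltage_trace(rep(-70, 10), dt = 5e-5)
  expect_s3_class(tr, "trace")
  expect_equal(trace_times(tr)[2] - trace_times(tr)[1], 5e-5)

  expect_error(field_sweep(rep(0, 100), 5e-5, stim_times = c(0.002, 0.001)),
               "increasing")
  expect_error(field_sweep(rep(0, 100), 5e-5, stim_times = 1), "span")
})

test_that("protocol validation rejects a missing required parameter for every kind", {
  required <- list(
    ramp = list(i_start = 0, i_end = 100, duration = 2),
    step = list(amplitude = -25, duration = 0.5),
    membrane_test = list(amplitude = 10, duration = 0.2),
    io_curve = list(intensities = c(10, 20, 30, 40)),
    paired_pulse = list(isi = 50),
    train = list(frequency = 5, n_pulses = 100),
    hfs = list(frequency = 100, duration = 1, n_trains = 2, inter_train = 20),
    depotentiation = list(frequency = 5, duration = 180, delay_after_hfs = 300),
    pp_lfs = list(frequency = 1, duration = 900, pair_isi = 50),
    sp_lfs = list(frequency = 1, duration = 900),
    baseline = list(duration = 1))
  for (kind in names(required)) {
    full <- required[[kind]]
    expect_s3_class(do.call(protocol_spec, c(list(kind = kind), full)),
                    "protocol_spec")
    for (drop in names(full)) {
      expect_error(do.call(protocol_spec, c(list(kind = kind),
                                            full[setdiff(names(full), drop)])),
                   "missing required", info = paste(kind, drop))
    }
  }
  expect_error(protocol_spec("train", frequency = -5, n_pulses = 10),
               "positive")
})

test_that("liquid junction correction shifts, composes and inverts", {
  tr <- voltage_trace(rep(-60, 100), dt = 5e-5)
  expect_equal(liquid_junction_correct(tr, 10)$v, rep(-70, 100))
  expect_equal(liquid_junction_correct(tr, 0)$v, tr$v)
  twice <- liquid_junction_correct(liquid_junction_correct(tr, 10), -10)
  expect_equal(twice$v, tr$v)
  expect_equal(twice$meta$ljp_correction_mV, 0)
})

test_that("sweep files round-trip through the delimited + sidecar dialect", {
  dir <- withr::local_tempdir()
  tr <- simulate_neuron(neuron_params(),
                        protocol_spec("baseline", duration = 0.05))
  csv <- file.path(dir, "sweep.csv")
  side <- write_sweep(tr, csv)
  back <- read_sweeps(csv, side)[[1]]
  expect_s3_class(back, "trace")
  expect_equal(back$dt, tr$dt, tolerance = 1e-12)
  expect_equal(back$v, tr$v, tolerance = 1e-9)
  expect_equal(back$i_cmd, tr$i_cmd, tolerance = 1e-9)
  expect_equal(back$meta$protocol$kind, "baseline")

  # declared dt without a time column
  sc2 <- file.path(dir, "side2.json")
  jsonlite::write_json(list(dt_s = 5e-5, type = "trace",
                            channels = data.frame(column = "v",
                                                  role = "voltage",
                                                  units = "mV")),
                       sc2, auto_unbox = TRUE, digits = NA)
  f2 <- file.path(dir, "v.csv")
  utils::write.csv(data.frame(v = rep(-70, 10)), f2, row.names = FALSE)
  expect_equal(read_sweeps(f2, sc2)[[1]]$dt, 5e-5)
})

test_that("unit declarations convert to internal mV/pA/s on ingest", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "volts.csv")
  utils::write.csv(data.frame(t = seq(0, 9) / 1000, v = rep(-0.07, 10)),
                   f, row.names = FALSE)
  sc <- file.path(dir, "volts.json")
  jsonlite::write_json(list(type = "trace",
                            channels = data.frame(column = c("t", "v"),
                                                  role = c("time", "voltage"),
                                                  units = c("s", "V"))),
                       sc, auto_unbox = TRUE, digits = NA)
  tr <- read_sweeps(f, sc)[[1]]
  expect_equal(tr$v, rep(-70, 10))
  expect_equal(tr$dt, 1e-3)
})

test_that("malformed sweep files are rejected as format errors", {
  dir <- withr::local_tempdir()
  sc <- file.path(dir, "side.json")
  jsonlite::write_json(list(type = "trace",
                            channels = data.frame(column = c("t", "v"),
                                                  role = c("time", "voltage"),
                                                  units = c("s", "mV"))),
                       sc, auto_unbox = TRUE, digits = NA)
  # empty file
  empty <- file.path(dir, "empty.csv")
  writeLines("t,v", empty)
  expect_error(read_sweeps(empty, sc), "format error")
  # jittered time stamps beyond 1% of dt
  jit <- file.path(dir, "jitter.csv")
  set.seed(7)
  t <- seq(0, 0.01, by = 5e-5) + runif(201, 0, 2e-6)
  utils::write.csv(data.frame(t = t, v = rep(-70, 201)), jit,
                   row.names = FALSE)
  expect_error(read_sweeps(jit, sc), "non-uniform")
  # neither dt nor time column
  sc3 <- file.path(dir, "side3.json")
  jsonlite::write_json(list(type = "trace",
                            channels = data.frame(column = "v",
                                                  role = "voltage",
                                                  units = "mV")),
                       sc3, auto_unbox = TRUE, digits = NA)
  f3 <- file.path(dir, "v3.csv")
  utils::write.csv(data.frame(v = rep(-70, 10)), f3, row.names = FALSE)
  expect_error(read_sweeps(f3, sc3), "neither dt_s nor a time column")
})

test_that("result tables reject duplicate keys and round-trip bit-exactly", {
  expect_error(result_table(unit = c("a", "a"), measure = c("m", "m"),
                            value = 1:2, units = "mV", group = "g"),
               "duplicate")
  dir <- withr::local_tempdir()
  set.seed(11)
  n <- 100
  tab <- result_table(unit = sprintf("c%03d", seq_len(n)), measure = "x",
                      value = rnorm(n) * 10^sample(-5:5, n, TRUE),
                      units = "mV", group = sample(c("a", "b"), n, TRUE))
  p <- file.path(dir, "res.csv")
  write_results(tab, p)
  back <- read_results(p)
  expect_identical(back$value, tab$value) # bit-exact for finite doubles
  expect_identical(back$unit, tab$unit)

  # one-row table: header + one line
  p2 <- file.path(dir, "one.csv")
  write_results(result_table("c1", "rmp", -76.2, "mV", "dorsal"), p2)
  expect_length(readLines(p2), 2L)

  # NaN serialized as an empty cell and read back as missing
  p3 <- file.path(dir, "nan.csv")
  write_results(result_table("c1", "fahp", NaN, "mV", "dorsal"), p3)
  expect_true(grepl(',"",|,,', readLines(p3)[2]))
  expect_true(is.na(read_results(p3)$value[1]))
})
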