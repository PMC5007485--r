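test_that("protocol constructors validate their fields", {
  act <- voltage_protocol("activation", holding_potential = -90,
                          step_voltages = seq(-100, 60, by = 10),
                          step_duration = 20)
  expect_equal(n_sweeps(act), 17)
  expect_error(voltage_protocol("activation", -90,
                                step_voltages = c(-20, -20, 0),
                                step_duration = 20),
               "strictly increasing")
  expect_error(voltage_protocol("activation", -90,
                                step_voltages = c(-20, 0),
                                step_duration = -1),
               "positive duration")
  expect_error(voltage_protocol("recovery", -90, step_duration = 20,
                                conditioning_duration = 200,
                                recovery_times = c(-1, 2, 4),
                                test_voltage = 0),
               ">= 0")
})

test_that("sweep_set rejects trace/protocol mismatches and empty matrices", {
  act <- default_protocols()$activation
  expect_error(sweep_set(0.02, matrix(0, 14, 100), act, 37),
               "17 sweeps")
  expect_error(sweep_set(0.02, matrix(numeric(0), 0, 0), act, 37),
               "at least one")
  ok <- sweep_set(0.02, matrix(rnorm(17 * 50), 17, 50), act, 40, "WT")
  expect_s3_class(ok, "sweep_set")
  expect_equal(sweep_times(ok)[2], 0.02)
})

test_that("sweep sets round-trip through disk losslessly", {
  truth <- default_truth(noise_sd = 0.02)
  pro <- voltage_protocol("recovery", -90, step_duration = 10,
                          conditioning_duration = 50,
                          recovery_times = c(0.5, 1, 2, 4, 8, 16, 32),
                          test_voltage = 0)
  sw <- generate_sweepset(truth, pro, dt = 0.05, seed = 11,
                          temperature = 40, condition_label = "A1273V")
  tf <- tempfile(fileext = ".csv"); mf <- tempfile(fileext = ".json")
  write_sweepset(sw, tf, mf)
  back <- read_sweepset(tf, mf)
  expect_equal(back$traces, sw$traces, tolerance = 0)
  expect_identical(back$temperature, 40)
  expect_identical(back$condition_label, "A1273V")
  expect_equal(back$protocol, sw$protocol)
  expect_equal(back$ground_truth, sw$ground_truth)

  # sweep-count mismatch between metadata and trace file is caught
  pro2 <- voltage_protocol("recovery", -90, step_duration = 10,
                           conditioning_duration = 50,
                           recovery_times = c(0.5, 1, 2, 4, 8, 16, 32, 64),
                           test_voltage = 0)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  meta$protocol <- nav11dyn:::protocol_to_list(pro2)
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(read_sweepset(tf, mf), "implies 8 sweeps")
})

test_that("trace files with defective time bases are rejected", {
  truth <- default_truth(noise_sd = 0)
  act <- default_protocols()$activation
  sw <- generate_sweepset(truth, act, dt = 0.05)
  tf <- tempfile(fileext = ".csv"); mf <- tempfile(fileext = ".json")
  write_sweepset(sw, tf, mf)
  df <- utils::read.csv(tf, check.names = FALSE)
  df$time_ms[3] <- df$time_ms[2]          # non-monotonic time
  utils::write.csv(df, tf, row.names = FALSE)
  expect_error(read_sweepset(tf, mf), "strictly increasing")
  names(df)[1] <- "t"                     # missing time column
  utils::write.csv(df, tf, row.names = FALSE)
  expect_error(read_sweepset(tf, mf), "time_ms")
})

test_that("condition presets load, reject unknown labels, and round-trip bit-identically", {
  expect_error(load_condition("WT38"), "unknown condition")
  for (lab in condition_labels()) {
    p <- load_condition(lab)
    f <- tempfile(fileext = ".json")
    write_condition(p, f)
    expect_identical(read_condition(f), p, label = lab)
  }
  # variant gating is depolarised relative to wild type at 37 C
  wt <- load_condition("WT37"); av <- load_condition("AV40")
  expect_gt(av$m_gate$v_half, wt$m_gate$v_half)
  expect_gt(av$h_gate$v_half, wt$h_gate$v_half)
})
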