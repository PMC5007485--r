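test_that("default protocols match the standard pulse design", {
  pro <- default_protocols()
  expect_equal(n_sweeps(pro$activation), 17)
  expect_equal(range(pro$activation$step_voltages), c(-100, 60))
  expect_true(all(c(-130, 10) %in% pro$ssfi$step_voltages))
  expect_equal(pro$ssfi$prepulse_duration, 200)
  expect_equal(pro$ssfi$test_voltage, 0)
  expect_equal(pro$recovery$conditioning_duration, 200)
  expect_equal(length(pro$recovery$recovery_times), 12)
  for (p in pro) expect_equal(p$holding_potential, -90)
})

test_that("gate relaxation follows the closed form", {
  truth <- default_truth()
  # long hold at the h midpoint: h settles to one half
  sched <- data.frame(voltage = truth$h_gate$v_half, duration = 500)
  g <- simulate_gates(truth, sched, dt = 0.05)
  expect_equal(g$h[length(g$h)], 0.5, tolerance = 1e-9)
  expect_true(all(g$m >= 0 & g$m <= 1))
  expect_true(all(g$h >= 0 & g$h <= 1))

  # starting at steady state, the trajectory is constant
  g2 <- simulate_gates(truth, data.frame(voltage = -20, duration = 5),
                       dt = 0.01)
  expect_equal(diff(range(g2$m)), 0, tolerance = 1e-12)
  expect_equal(diff(range(g2$h)), 0, tolerance = 1e-12)
})

test_that("segment splitting does not change gate endpoints (semigroup property)", {
  truth <- default_truth()
  for (V in c(-80, -40, 0)) {
    one <- simulate_gates(truth, data.frame(voltage = V, duration = 8),
                          dt = 0.01, m0 = 0.1, h0 = 0.9)
    two <- simulate_gates(truth,
                          data.frame(voltage = c(V, V), duration = c(3, 5)),
                          dt = 0.01, m0 = 0.1, h0 = 0.9)
    n <- nrow(one)
    expect_equal(two$m[n], one$m[n], tolerance = 1e-12)
    expect_equal(two$h[n], one$h[n], tolerance = 1e-12)
  }
  # endpoints are independent of the sampling interval
  co <- simulate_gates(truth, data.frame(voltage = -30, duration = 7.7),
                       dt = 0.7, m0 = 0.2, h0 = 0.8)
  fi <- simulate_gates(truth, data.frame(voltage = -30, duration = 7.7),
                       dt = 0.007, m0 = 0.2, h0 = 0.8)
  expect_equal(co$m[nrow(co)], fi$m[nrow(fi)], tolerance = 1e-10)
})

test_that("synthetic sweep sets are reproducible and physically sensible", {
  truth <- default_truth()
  act <- default_protocols()$activation
  a1 <- generate_sweepset(truth, act, seed = 7)
  a2 <- generate_sweepset(truth, act, seed = 7)
  a3 <- generate_sweepset(truth, act, seed = 8)
  expect_identical(a1$traces, a2$traces)
  expect_false(identical(a1$traces, a3$traces))
  expect_s3_class(a1$ground_truth, "true_channel_params")

  # a step exactly at the reversal potential carries zero mean current
  pro0 <- voltage_protocol("activation", -90,
                           step_voltages = c(truth$e_rev - 40, truth$e_rev),
                           step_duration = 20)
  s0 <- generate_sweepset(truth, pro0, noise_sd = 0)
  expect_equal(max(abs(s0$traces[2, ])), 0)

  # peak inward current first grows then shrinks toward the reversal
  pk <- peak_currents(generate_sweepset(truth, act, noise_sd = 0))
  i_min <- which.min(pk)
  expect_gt(i_min, 1)
  expect_lt(i_min, length(pk))
  expect_true(all(diff(pk[i_min:length(pk)]) > 0))
})

test_that("ssfi availability saturates and recovery is monotone", {
  truth <- default_truth()
  pro <- default_protocols()
  ssfi <- generate_sweepset(truth, pro$ssfi, noise_sd = 0)
  t <- sweep_times(ssfi)
  test_win <- t >= pro$ssfi$prepulse_duration
  pk <- apply(abs(ssfi$traces[, test_win]), 1, max)
  norm <- pk / max(pk)
  expect_gt(norm[1], 0.995)              # full availability at -130 mV
  expect_lt(norm[length(norm)], 0.01)    # none after a +10 mV prepulse
  expect_true(all(diff(norm) < 1e-6))

  # monotone up to the sub-sample jitter of peak localisation on the grid
  rec <- generate_sweepset(truth, pro$recovery, noise_sd = 0)
  fr <- fit_recovery(rec)
  expect_true(all(diff(fr$fractions) > -1e-3))
  expect_gt(fr$fractions[length(fr$fractions)], 0.98)
})
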