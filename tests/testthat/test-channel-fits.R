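test_that("boltzmann_value obeys midpoint, closed-form and limit identities", {
  bz <- boltzmann_params(-39.0, 7.4)
  expect_equal(boltzmann_value(-39.0, bz), 0.5)
  expect_equal(boltzmann_value(-39.0 + 7.4 * log(3), bz), 0.75)
  fall <- boltzmann_params(-43.3, -4.0)
  expect_equal(boltzmann_value(1e4, fall), 0, tolerance = 1e-12)
  expect_equal(boltzmann_value(-1e4, fall), 1, tolerance = 1e-12)
  expect_error(boltzmann_params(-39, 0), "non-zero")
})

test_that("peak extraction respects the blanking window", {
  act <- voltage_protocol("activation", -90, step_voltages = c(-20, 0),
                          step_duration = 2)
  tr <- matrix(0, 2, 100)
  tr[1, 40] <- -5
  tr[2, 4] <- -9          # inside the 0.2 ms blank at dt = 0.05
  tr[2, 60] <- -3
  sw <- sweep_set(0.05, tr, act, 37)
  expect_equal(peak_currents(sw, blank_ms = 0.2), c(-5, -3))
  expect_error(peak_currents(sw, blank_ms = 10), "longer than the sweep")
  sw0 <- sweep_set(0.05, matrix(0, 2, 100), act, 37)
  expect_error(peak_currents(sw0), "all-zero")
})

test_that("time to half-peak interpolates between samples", {
  # linear ramp 0 -> -1 nA over 2 ms crosses half-peak at exactly 1 ms
  dt <- 0.1
  ramp <- seq(0, -1, length.out = 21)
  expect_equal(time_to_half_peak(ramp, dt), 1.0)
  # sub-sample crossing agrees with a 10x oversampled version of the trace
  t <- seq(0, 5, by = 0.05)
  tr <- -(1 - exp(-t / 0.3)) * exp(-t / 1.7)
  t10 <- seq(0, 5, by = 0.005)
  tr10 <- -(1 - exp(-t10 / 0.3)) * exp(-t10 / 1.7)
  expect_lt(abs(time_to_half_peak(tr, 0.05) -
                  time_to_half_peak(tr10, 0.005)), 0.005)
  expect_error(time_to_half_peak(rep(0, 50), 0.05), "flat trace")
})

test_that("conductance conversion divides by driving force and excludes the reversal", {
  cc <- conductance_curve(c(-1, -2), c(0, 20), v_rev = 50)
  expect_equal(cc$G[1], 0.02)
  expect_equal(max(cc$G_norm), 1)
  expect_warning(conductance_curve(c(-1, -0.01, 1), c(0, 50, 60), v_rev = 50),
                 "dropping 1")
  suppressWarnings(
    expect_error(conductance_curve(c(-1), c(50), v_rev = 50), "all points"))
})

test_that("reversal potential is interpolated from the peak I-V zero crossing", {
  v <- seq(-40, 60, by = 10)
  g <- 1 / (1 + exp(-(v + 20) / 7))
  pk <- g * (v - 52.3)
  expect_equal(estimate_reversal(pk, v), 52.3, tolerance = 0.5)
  expect_true(is.na(estimate_reversal(pk[v < 40], v[v < 40])))
})

test_that("Boltzmann fitting recovers exact curves and enforces preconditions", {
  v <- seq(-90, 10, by = 5)
  bz <- boltzmann_params(-43.3, -4.0)
  fit <- fit_boltzmann(v, boltzmann_value(v, bz), "falling")
  expect_equal(fit$v_half, -43.3, tolerance = 1e-6)
  expect_equal(fit$slope, -4.0, tolerance = 1e-6)
  expect_error(fit_boltzmann(v, rep(0.5, length(v)), "rising"), "range")
  expect_error(fit_boltzmann(v[1:3], c(0, 0.5, 1), "rising"), "4 points")
})

test_that("Boltzmann fitting is voltage-shift equivariant", {
  set.seed(42)
  v <- seq(-80, 0, by = 5)
  for (i in 1:5) {
    vh <- stats::runif(1, -60, -25)
    sl <- stats::runif(1, 4, 9)
    y <- boltzmann_value(v, boltzmann_params(vh, sl)) +
      stats::rnorm(length(v), sd = 0.01)
    shift <- stats::runif(1, -20, 20)
    f0 <- fit_boltzmann(v, y, "rising")
    f1 <- fit_boltzmann(v + shift, y, "rising")
    expect_equal(f1$v_half - f0$v_half, shift, tolerance = 1e-5)
    expect_equal(f1$slope, f0$slope, tolerance = 1e-6)
  }
})

test_that("single-exponential decay fits recover tau and reject rising segments", {
  t <- seq(0, 8, by = 0.02)
  tr <- -2 * exp(-t / 0.8)
  fit <- fit_single_exp_decay(tr, 0.02)
  expect_equal(fit$tau, 0.8, tolerance = 1e-6)
  # two-component decay: fitted tau lies between the true constants
  tr2 <- -(1.5 * exp(-t / 0.5) + 0.5 * exp(-t / 3))
  fit2 <- fit_single_exp_decay(tr2, 0.02)
  expect_gt(fit2$tau, 0.5)
  expect_lt(fit2$tau, 3)
  expect_error(fit_single_exp_decay(-rev(tr), 0.02), "peak")
})

test_that("double-exponential recovery fits separate fast and slow components", {
  t <- c(0.5, 1, 2, 4, 8, 16, 32, 64, 128, 256, 512)
  y <- 0.02 + 0.6 * (1 - exp(-t / 2)) + 0.35 * (1 - exp(-t / 50))
  fit <- fit_recovery_curve(y, t)
  expect_false(fit$fallback_single)
  expect_equal(fit$tau_fast, 2, tolerance = 1e-4)
  expect_equal(fit$tau_slow, 50, tolerance = 1e-4)
  expect_equal(fit$A_fast, 0.6, tolerance = 1e-4)
  expect_equal(fit$A_slow, 0.35, tolerance = 1e-4)
  expect_lt(fit$tau_fast, fit$tau_slow)
  # amplitudes and offset sum to the asymptote on noiseless data
  expect_equal(fit$offset + fit$A_fast + fit$A_slow, 0.97, tolerance = 1e-3)

  # effectively single-exponential data fall back with a flag
  y1 <- 0.05 + 0.9 * (1 - exp(-t / 5))
  fit1 <- fit_recovery_curve(y1, t)
  expect_true(fit1$fallback_single)
  expect_equal(fit1$tau_fast, 5, tolerance = 1e-3)
  expect_error(fit_recovery_curve(y1[1:4], t[1:4]), "6 recovery")
})

test_that("noiseless generator-fitter round trip recovers the gating truth", {
  truth <- true_channel_params(m_gate = boltzmann_params(-20, 7))
  pro <- default_protocols()
  fa <- fit_activation(generate_sweepset(truth, pro$activation, noise_sd = 0))
  expect_lt(abs(fa$boltzmann$v_half - (-20)), 0.5)
  expect_lt(abs(fa$v_rev - 55), 1)
  expect_equal(max(fa$curve$G_norm), 1)
  fs <- fit_ssfi(generate_sweepset(truth, pro$ssfi, noise_sd = 0))
  expect_lt(abs(fs$boltzmann$v_half - (-60)), 0.5)
  expect_lt(abs(fs$boltzmann$slope - (-6)), 0.3)
  # open-state inactivation time constants decrease with depolarisation
  dc <- fit_decay_curve(generate_sweepset(truth, pro$activation, noise_sd = 0),
                        voltages = c(-10, 0, 10, 20))
  expect_true(all(diff(dc$tau) < 0))
  expect_lt(abs(dc$tau[dc$voltage == 0] / truth_tau_h(truth, 0) - 1), 0.15)
})
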