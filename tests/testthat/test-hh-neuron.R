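test_that("derivatives vanish at constructed equilibria", {
  p <- leak_only_params()
  st <- initial_state(p)           # V = E_L, gates at steady state
  d <- hh_derivatives(st, p, I_stim = 0)
  expect_equal(d[1], 0)            # leak-only at E_L: no net current
  expect_equal(d[2], 0)            # m at its steady state
  expect_equal(d[3], 0)
  expect_equal(d[4], 0)
})

test_that("derivatives match a hand-computed current balance", {
  p <- load_condition("WT37")
  V <- -65; m <- 0.2; h <- 0.6; n <- 0.3; I <- 2
  d <- hh_derivatives(c(V, m, h, n), p, I)
  # independent arithmetic: Table-row numerals, capacitance 1 uF/cm^2
  i_leak <- 0.0205 * (V - (-70.3))
  i_na <- 56 * m^3 * h * (V - 50)
  i_k <- 5 * n^4 * (V - (-90))
  expect_equal(d[1], (I - i_leak - i_na - i_k) / 1.0, tolerance = 1e-12)
})

test_that("compiled and pure-R right-hand sides agree", {
  for (lab in condition_labels()) {
    p <- load_condition(lab)
    y0 <- c(-62.5, 0.1, 0.7, 0.2)
    # one RK4 step computed in R from hh_derivatives
    dt <- 0.01
    k1 <- hh_derivatives(y0, p, 3)
    k2 <- hh_derivatives(y0 + dt / 2 * k1, p, 3)
    k3 <- hh_derivatives(y0 + dt / 2 * k2, p, 3)
    k4 <- hh_derivatives(y0 + dt * k3, p, 3)
    y_r <- y0 + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    sim <- simulate_neuron(p, 3, duration = dt, dt = dt, method = "rk4",
                           init = y0)
    y_c <- as.numeric(sim[nrow(sim), c("V", "m", "h", "n")])
    expect_equal(y_c, unname(y_r), tolerance = 1e-12, label = lab)
  }
})

test_that("zero stimulus settles near rest without spikes", {
  p <- load_condition("WT37")
  sim <- simulate_neuron(p, 0, duration = 500, dt = 0.01, method = "rk4",
                         keep_every = 10L)
  sp <- detect_spikes(sim)
  expect_length(sp$spike_times, 0)
  expect_false(sp$blocked)
  # rest sits a few mV above E_L (sodium window current); well below threshold
  expect_lt(abs(sim$V[nrow(sim)] - p$E_L), 4)
})

test_that("adaptive and fixed-step integration agree on spike counts", {
  p <- load_condition("WT37")
  a <- simulate_neuron(p, 1, duration = 400, dt = 0.02, method = "lsoda")
  b <- simulate_neuron(p, 1, duration = 400, dt = 0.005, method = "rk4",
                       keep_every = 4L)
  expect_equal(length(detect_spikes(a)$spike_times),
               length(detect_spikes(b)$spike_times))
})

test_that("spike detection counts threshold crossings and flags plateaus", {
  mk_sim <- function(V, dt = 0.1) {
    structure(data.frame(time = seq_along(V) * dt - dt, V = V,
                         m = 0, h = 0, n = 0),
              class = c("sim_result", "data.frame"),
              I_stim = 0, params_label = "fixture", dt = dt)
  }
  expect_length(detect_spikes(mk_sim(rep(-70, 1000)))$spike_times, 0)
  expect_false(detect_spikes(mk_sim(rep(-70, 1000)))$blocked)
  # ten well-separated triangular spikes
  one <- c(rep(-70, 80), seq(-70, 30, length.out = 10),
           seq(30, -70, length.out = 10))
  sp <- detect_spikes(mk_sim(rep(one, 10)), discard_frac = 0)
  expect_length(sp$spike_times, 10)
  # depolarised plateau with no oscillation is classified as blocked
  plateau <- detect_spikes(mk_sim(rep(-20, 1000)))
  expect_true(plateau$blocked)
})

test_that("gates stay within [0,1] across conditions and stimuli", {
  for (lab in c("WT37", "AV40")) {
    p <- load_condition(lab)
    for (I in c(0.2, 45)) {
      sim <- simulate_neuron(p, I, duration = 300, dt = 0.005,
                             method = "rk4", keep_every = 10L)
      expect_true(all(sim$m >= 0 & sim$m <= 1), label = paste(lab, I))
      expect_true(all(sim$h >= 0 & sim$h <= 1))
      expect_true(all(sim$n >= 0 & sim$n <= 1))
      expect_true(all(is.finite(sim$V)))
    }
  }
})

test_that("f-I curves are flat for a passive membrane and graded for WT37", {
  f0 <- fi_curve(leak_only_params(), c(1, 5, 20), settle = 50, window = 100)
  expect_true(all(f0$rate == 0))
  f <- fi_curve(load_condition("WT37"), seq(0.5, 8, by = 1.5),
                settle = 200, window = 400)
  expect_true(all(diff(f$rate) >= 0))
  expect_gt(f$rate[length(f$rate)], 50)
})
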