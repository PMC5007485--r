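#' Default voltage-clamp protocols
#'
#' The three standard Na-channel protocols: 20 ms activation steps from
#' -100 to +60 mV in 10 mV increments; steady-state fast inactivation with
#' 200 ms prepulses from -130 to +10 mV followed by a 0 mV test pulse; and
#' double-pulse recovery (200 ms conditioning at 0 mV, recovery at the
#' -90 mV holding potential over a log-spaced ladder of 12 intervals from
#' 0.5 to 512 ms, 0 mV test pulse).
#'
#' @return Named list of [voltage_protocol()]: `activation`, `ssfi`,
#'   `recovery`.
#' @export
default_protocols <- function() {
  list(
    activation = voltage_protocol("activation",
                                  holding_potential = -90,
                                  step_voltages = seq(-100, 60, by = 10),
                                  step_duration = 20),
    ssfi = voltage_protocol("ssfi",
                            holding_potential = -90,
                            step_voltages = seq(-130, 10, by = 10),
                            step_duration = 20,
                            prepulse_duration = 200,
                            test_voltage = 0),
    recovery = voltage_protocol("recovery",
                                holding_potential = -90,
                                step_duration = 20,
                                conditioning_duration = 200,
                                recovery_times = 0.5 * 2^seq(0, 10, length.out = 12),
                                test_voltage = 0)
  )
}

# steady state and time constant of one synthetic gate at voltage V.
# The ground-truth m_gate Boltzmann specifies the macroscopic
# conductance-voltage relation (the quantity the analysis stage
# estimates); since the channel opens as m^3 h, the per-particle steady
# state is the cube root of that curve.
gate_inf <- function(V, gate, exponent = 1) {
  (1 / (1 + exp(-(V - gate$v_half) / gate$slope)))^(1 / exponent)
}
gate_tau <- function(V, gate, tau_base, tau_floor) {
  tau_base / cosh((V - gate$v_half) / (2 * gate$slope)) + tau_floor
}

#' Closed-form gate trajectories under a piecewise-constant voltage schedule
#'
#' Within each constant-voltage segment the gates relax exponentially
#' toward their steady state,
#' \eqn{x(t) = x_\infty + (x_0 - x_\infty) e^{-t/\tau_x(V)}}.  The h
#' steady state is the ground-truth availability Boltzmann; the m steady
#' state is the cube root of the ground-truth conductance Boltzmann, so
#' that the open fraction \eqn{m^3} reproduces that curve.  Segment
#' endpoints are propagated in closed form from the exact segment
#' durations, so endpoint values are independent of `dt`.
#'
#' @param truth A [true_channel_params()].
#' @param voltage_schedule data.frame with columns `voltage` (mV) and
#'   `duration` (ms), one row per segment.
#' @param dt Sample interval (ms).
#' @param m0,h0 Initial gate values in `[0,1]`; default is steady state at
#'   the first segment's voltage.
#' @return data.frame of class `gate_trajectory` with columns `time`,
#'   `voltage`, `m`, `h`; samples lie on the dt grid over the schedule.
#' @export
simulate_gates <- function(truth, voltage_schedule, dt, m0 = NULL, h0 = NULL) {
  stopifnot(inherits(truth, "true_channel_params"), dt > 0,
            is.data.frame(voltage_schedule),
            all(c("voltage", "duration") %in% names(voltage_schedule)),
            all(voltage_schedule$duration > 0))
  segs <- voltage_schedule
  if (is.null(m0)) m0 <- gate_inf(segs$voltage[1], truth$m_gate, 3)
  if (is.null(h0)) h0 <- gate_inf(segs$voltage[1], truth$h_gate)

  total <- sum(segs$duration)
  time <- seq(0, total, by = dt)
  starts <- cumsum(c(0, segs$duration))
  m <- numeric(length(time)); h <- numeric(length(time))
  volt <- numeric(length(time))
  mseg <- m0; hseg <- h0
  for (k in seq_len(nrow(segs))) {
    V <- segs$voltage[k]
    minf <- gate_inf(V, truth$m_gate, 3)
    hinf <- gate_inf(V, truth$h_gate)
    tm <- gate_tau(V, truth$m_gate, truth$tau_m_base, truth$tau_m_floor)
    th <- gate_tau(V, truth$h_gate, truth$tau_h_base, truth$tau_h_floor)
    if (!is.finite(tm) || !is.finite(th) || tm <= 0 || th <= 0)
      stop("non-finite or non-positive gate time constant")
    last <- k == nrow(segs)
    idx <- which(time >= starts[k] & (time < starts[k + 1] | last))
    rel <- time[idx] - starts[k]
    m[idx] <- minf + (mseg - minf) * exp(-rel / tm)
    h[idx] <- hinf + (hseg - hinf) * exp(-rel / th)
    volt[idx] <- V
    # exact endpoint propagation, independent of the sampling grid
    mseg <- minf + (mseg - minf) * exp(-segs$duration[k] / tm)
    hseg <- hinf + (hseg - hinf) * exp(-segs$duration[k] / th)
  }
  structure(data.frame(time = time, voltage = volt, m = m, h = h),
            class = c("gate_trajectory", "data.frame"))
}

# per-sweep piecewise-constant schedules; t = 0 is the first pulse onset
# (gates are initialised at holding steady state separately)
protocol_schedules <- function(protocol) {
  hp <- protocol$holding_potential
  switch(protocol$kind,
    activation = lapply(protocol$step_voltages, function(v)
      data.frame(voltage = v, duration = protocol$step_duration)),
    ssfi = lapply(protocol$step_voltages, function(v)
      data.frame(voltage = c(v, protocol$test_voltage),
                 duration = c(protocol$prepulse_duration,
                              protocol$step_duration))),
    recovery = {
      maxrt <- max(protocol$recovery_times)
      lapply(protocol$recovery_times, function(rt) {
        # pad after the test pulse so every sweep spans the same total time
        segs <- data.frame(
          voltage = c(protocol$test_voltage, hp, protocol$test_voltage, hp),
          duration = c(protocol$conditioning_duration, rt,
                       protocol$step_duration, maxrt - rt + 1))
        segs[segs$duration > 0, ]
      })
    })
}

#' Generate a synthetic voltage-clamp sweep set
#'
#' Synthesises whole-cell Na currents
#' \eqn{I(t) = g_{max}\, m(t)^3 h(t)\, (V - E_{rev})} from closed-form
#' gate relaxation under one of the three standard protocols, plus
#' i.i.d. Gaussian noise.  Each sweep starts (t = 0 at the first pulse
#' onset) from gate steady state at the holding potential.  With
#' `noise_sd = 0` the traces are deterministic; with a fixed `seed` they
#' are reproducible.
#'
#' @param truth A [true_channel_params()].
#' @param protocol A [voltage_protocol()].
#' @param dt Sample interval (ms); default 0.02 (50 kHz).
#' @param noise_sd Noise standard deviation (nA); `NULL` uses the truth's
#'   `noise_sd`, and if that is `NULL` too, 1% of the peak absolute
#'   noiseless current.
#' @param seed Integer seed for the noise; required unless `noise_sd = 0`.
#' @param temperature,condition_label Metadata carried on the result.
#' @return A [sweep_set()] with `ground_truth` attached.
#' @export
generate_sweepset <- function(truth, protocol, dt = 0.02, noise_sd = NULL,
                              seed = NULL, temperature = 37,
                              condition_label = "synthetic") {
  stopifnot(inherits(truth, "true_channel_params"),
            inherits(protocol, "voltage_protocol"))
  if (is.null(noise_sd)) noise_sd <- truth$noise_sd
  hp <- protocol$holding_potential
  m0 <- gate_inf(hp, truth$m_gate, 3)
  h0 <- gate_inf(hp, truth$h_gate)
  schedules <- protocol_schedules(protocol)
  clean <- lapply(schedules, function(s) {
    g <- simulate_gates(truth, s, dt, m0 = m0, h0 = h0)
    truth$g_max * g$m^3 * g$h * (g$voltage - truth$e_rev)
  })
  nsamp <- min(lengths(clean))
  traces <- do.call(rbind, lapply(clean, function(x) x[seq_len(nsamp)]))
  if (is.null(noise_sd)) noise_sd <- 0.01 * max(abs(traces))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    set.seed(seed)
    traces <- traces + matrix(stats::rnorm(length(traces), sd = noise_sd),
                              nrow = nrow(traces))
  }
  truth$noise_sd <- noise_sd
  sweep_set(dt = dt, traces = traces, protocol = protocol,
            temperature = temperature, condition_label = condition_label,
            ground_truth = truth)
}
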