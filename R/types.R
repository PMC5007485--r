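#' Boltzmann gating parameters
#'
#' Midpoint and slope of a sigmoid gating curve
#' \eqn{x_\infty(V) = 1 / (1 + \exp(-(V - V_{1/2})/s))}.  With this
#' convention a positive slope gives an increasing curve (activation) and a
#' negative slope a decreasing one (availability / fast inactivation).
#'
#' @param v_half Midpoint voltage (mV).
#' @param slope Slope factor (mV, signed); must be non-zero.
#' @return An object of class `boltzmann_params`.
#' @export
boltzmann_params <- function(v_half, slope) {
  stopifnot(is.numeric(v_half), length(v_half) == 1, is.finite(v_half),
            is.numeric(slope), length(slope) == 1, is.finite(slope))
  if (slope == 0) stop("Boltzmann slope must be non-zero")
  structure(list(v_half = v_half, slope = slope), class = "boltzmann_params")
}

#' @export
print.boltzmann_params <- function(x, ...) {
  cat(sprintf("Boltzmann: V_half = %.3f mV, slope = %.3f mV (%s)\n",
              x$v_half, x$slope,
              if (x$slope > 0) "rising" else "falling"))
  invisible(x)
}

#' Voltage-clamp pulse protocol
#'
#' Describes one of the three standard Na-channel protocols:
#' \describe{
#'   \item{activation}{depolarising steps from holding, one sweep per step
#'     voltage.}
#'   \item{ssfi}{steady-state fast inactivation: long prepulse to each of
#'     `step_voltages`, followed by a fixed test pulse.}
#'   \item{recovery}{double pulse: conditioning depolarisation, recovery
#'     interval of varying length at holding, then a test pulse.}
#' }
#'
#' @param kind One of `"activation"`, `"ssfi"`, `"recovery"`.
#' @param holding_potential Holding potential between pulses (mV).
#' @param step_voltages Step (activation) or prepulse (ssfi) voltages, mV,
#'   strictly increasing.
#' @param step_duration Duration of the step / test pulse (ms).
#' @param prepulse_duration Prepulse duration (ms), ssfi only.
#' @param conditioning_duration Conditioning pulse duration (ms), recovery
#'   only.
#' @param recovery_times Recovery intervals (ms), recovery only, strictly
#'   increasing and non-negative.
#' @param test_voltage Test-pulse voltage (mV), ssfi and recovery.
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(kind,
                             holding_potential,
                             step_voltages = NULL,
                             step_duration = NULL,
                             prepulse_duration = NULL,
                             conditioning_duration = NULL,
                             recovery_times = NULL,
                             test_voltage = NULL) {
  kind <- match.arg(kind, c("activation", "ssfi", "recovery"))
  stopifnot(is.numeric(holding_potential), length(holding_potential) == 1)
  chk_dur <- function(x, nm) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || x <= 0)
      stop(sprintf("'%s' must be a single positive duration (ms)", nm))
  }
  chk_incr <- function(x, nm) {
    if (is.null(x) || length(x) < 1 || anyNA(x) || any(diff(x) <= 0))
      stop(sprintf("'%s' must be strictly increasing", nm))
  }
  chk_dur(step_duration, "step_duration")
  if (kind %in% c("activation", "ssfi")) chk_incr(step_voltages, "step_voltages")
  if (kind == "ssfi") {
    chk_dur(prepulse_duration, "prepulse_duration")
    stopifnot(is.numeric(test_voltage), length(test_voltage) == 1)
  }
  if (kind == "recovery") {
    chk_dur(conditioning_duration, "conditioning_duration")
    chk_incr(recovery_times, "recovery_times")
    if (any(recovery_times < 0)) stop("'recovery_times' must be >= 0")
    stopifnot(is.numeric(test_voltage), length(test_voltage) == 1)
  }
  structure(list(kind = kind,
                 holding_potential = holding_potential,
                 step_voltages = step_voltages,
                 step_duration = step_duration,
                 prepulse_duration = prepulse_duration,
                 conditioning_duration = conditioning_duration,
                 recovery_times = recovery_times,
                 test_voltage = test_voltage),
            class = "voltage_protocol")
}

#' Number of sweeps implied by a protocol
#'
#' @param protocol A [voltage_protocol()].
#' @return Integer sweep count (one per step voltage, or one per recovery
#'   time).
#' @export
n_sweeps <- function(protocol) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (protocol$kind == "recovery") length(protocol$recovery_times)
  else length(protocol$step_voltages)
}

#' Ground-truth channel parameters for the synthetic generator
#'
#' Defines the two-gate (m^3 h) channel used to synthesise voltage-clamp
#' currents.  Gate steady states are Boltzmann curves; gate time constants
#' are bell-shaped in voltage,
#' \eqn{\tau_x(V) = \tau_{base}/\cosh((V - V_{1/2})/(2 s)) + \tau_{floor}}.
#'
#' @param g_max Maximal conductance (uS); positive.
#' @param e_rev Reversal potential (mV).
#' @param m_gate,h_gate [boltzmann_params()] for activation (rising) and
#'   fast inactivation (falling).  `m_gate` parameterises the macroscopic
#'   conductance-voltage relation; the per-particle steady state used in
#'   the `m^3 h` synthesis is its cube root.
#' @param tau_m_base,tau_m_floor,tau_h_base,tau_h_floor Time-constant scale
#'   and floor for each gate (ms).
#' @param noise_sd Additive Gaussian noise on current (nA); `NULL` means
#'   "1% of peak absolute current" at generation time.
#' @return An object of class `true_channel_params`.
#' @export
true_channel_params <- function(g_max = 0.1,
                                e_rev = 55,
                                m_gate = boltzmann_params(-25, 7),
                                h_gate = boltzmann_params(-60, -6),
                                tau_m_base = 0.05, tau_m_floor = 0.015,
                                tau_h_base = 30, tau_h_floor = 6,
                                noise_sd = NULL) {
  stopifnot(g_max > 0, inherits(m_gate, "boltzmann_params"),
            inherits(h_gate, "boltzmann_params"),
            tau_m_base > 0, tau_m_floor > 0, tau_h_base > 0, tau_h_floor > 0)
  if (m_gate$slope <= 0) stop("m_gate must be rising (slope > 0)")
  if (h_gate$slope >= 0) stop("h_gate must be falling (slope < 0)")
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(g_max = g_max, e_rev = e_rev,
                 m_gate = m_gate, h_gate = h_gate,
                 tau_m_base = tau_m_base, tau_m_floor = tau_m_floor,
                 tau_h_base = tau_h_base, tau_h_floor = tau_h_floor,
                 noise_sd = noise_sd),
            class = "true_channel_params")
}

#' A set of voltage-clamp current sweeps on a shared time base
#'
#' @param dt Sampling interval (ms/sample), positive.
#' @param traces Numeric matrix, one row per sweep, current in nA.
#' @param protocol The [voltage_protocol()] that elicited the sweeps; the
#'   row count of `traces` must equal [n_sweeps()] of the protocol.
#' @param temperature Recording temperature (degrees C).
#' @param condition_label Free-text condition label (e.g. `"WT"`,
#'   `"A1273V"`).
#' @param ground_truth Optional [true_channel_params()] for synthetic data.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(dt, traces, protocol, temperature,
                      condition_label = "unknown", ground_truth = NULL) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0,
            is.matrix(traces), is.numeric(traces),
            inherits(protocol, "voltage_protocol"),
            is.numeric(temperature), length(temperature) == 1)
  if (nrow(traces) == 0 || ncol(traces) == 0)
    stop("'traces' must contain at least one sweep and one sample")
  if (nrow(traces) != n_sweeps(protocol))
    stop(sprintf("protocol implies %d sweeps but traces has %d rows",
                 n_sweeps(protocol), nrow(traces)))
  if (!is.null(ground_truth))
    stopifnot(inherits(ground_truth, "true_channel_params"))
  structure(list(dt = dt, traces = traces, protocol = protocol,
                 temperature = temperature,
                 condition_label = condition_label,
                 ground_truth = ground_truth),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("sweep_set: %d sweeps x %d samples (dt = %g ms), %s protocol, %s at %g C%s\n",
              nrow(x$traces), ncol(x$traces), x$dt, x$protocol$kind,
              x$condition_label, x$temperature,
              if (is.null(x$ground_truth)) "" else ", with ground truth"))
  invisible(x)
}

#' Sweep time base
#'
#' @param sweeps A [sweep_set()].
#' @return Sample times in ms, starting at 0.
#' @export
sweep_times <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  (seq_len(ncol(sweeps$traces)) - 1) * sweeps$dt
}
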