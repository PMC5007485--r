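#' @useDynLib nav11dyn, .registration = TRUE
NULL

# Pack a neuron_params + stimulus into the 14-double parameter block used
# by the compiled RHS.  Capacitance is converted from the table's uF/mm^2
# to uF/cm^2 (x100) so that mS/cm^2 conductances, mV and ms are
# dimensionally consistent; stimulus numerals are used verbatim.
pack_params <- function(params, I_stim) {
  stopifnot(inherits(params, "neuron_params"))
  c(params$g_L, params$g_K, params$g_Na,
    params$E_L, params$E_K, params$E_Na,
    params$C * 100, params$V_t,
    params$m_gate$v_half, params$m_gate$slope,
    params$h_gate$v_half, params$h_gate$slope,
    h_rate_shift(params), I_stim)
}

#' Time derivative of the membrane state
#'
#' Pure-R reference implementation of the model right-hand side:
#' \deqn{C dV/dt = I_{stim} - g_L(V-E_L) - g_{Na} m^3 h (V-E_{Na}) - g_K n^4 (V-E_K)}
#' with \eqn{dx/dt = (x_\infty(V) - x)/\tau_x(V)} for m and h (Boltzmann
#' steady states from the condition parameters, time constants
#' \eqn{1/(\alpha+\beta)} from the baseline rates; the h rates are
#' evaluated at a voltage shifted by the condition's total inactivation
#' shift) and full baseline alpha/beta kinetics for n.
#'
#' @param state Numeric vector `c(V, m, h, n)`.
#' @param params A [neuron_params()].
#' @param I_stim Stimulus current.
#' @return Numeric vector of derivatives (mV/ms, 1/ms).
#' @export
hh_derivatives <- function(state, params, I_stim = 0) {
  V <- state[1]; m <- state[2]; h <- state[3]; n <- state[4]
  r <- baseline_rate_functions(V, params$V_t)
  rh <- baseline_rate_functions(V - h_rate_shift(params), params$V_t)
  m_inf <- boltzmann_value(V, params$m_gate)
  h_inf <- boltzmann_value(V, params$h_gate)
  Cm <- params$C * 100  # uF/mm^2 -> uF/cm^2
  dV <- (I_stim - params$g_L * (V - params$E_L) -
           params$g_Na * m^3 * h * (V - params$E_Na) -
           params$g_K * n^4 * (V - params$E_K)) / Cm
  unname(c(dV,
           (m_inf - m) * (r$alpha_m + r$beta_m),
           (h_inf - h) * (rh$alpha_h + rh$beta_h),
           r$alpha_n * (1 - n) - r$beta_n * n))
}

#' Resting initial state for a condition
#'
#' @param params A [neuron_params()].
#' @param V Initial membrane potential (mV); defaults to the leak
#'   reversal.
#' @return `c(V, m, h, n)` with gates at their steady state for `V`.
#' @export
initial_state <- function(params, V = params$E_L) {
  r <- baseline_rate_functions(V, params$V_t)
  c(V = V,
    m = boltzmann_value(V, params$m_gate),
    h = boltzmann_value(V, params$h_gate),
    n = r$alpha_n / (r$alpha_n + r$beta_n))
}

#' Simulate the membrane response to a constant stimulus
#'
#' Integrates the four-state model either with the adaptive stiff-capable
#' `lsoda` solver (compiled right-hand side, relative/absolute tolerances
#' 1e-8/1e-10) or with a fixed-step fourth-order Runge-Kutta scheme for
#' bitwise-reproducible runs.
#'
#' @param params A [neuron_params()].
#' @param I_stim Stimulus current (table units).
#' @param duration Run length (ms).
#' @param dt Output sampling interval for `lsoda`, or the integration step
#'   for `rk4` (ms).
#' @param method `"lsoda"` or `"rk4"`.
#' @param init Initial state `c(V, m, h, n)`; default [initial_state()].
#' @param rtol,atol Solver tolerances (`lsoda` only).
#' @param keep_every For `rk4`: keep every k-th step in the output.
#' @return An object of class `sim_result`: data.frame columns `time`,
#'   `V`, `m`, `h`, `n`, with attributes `I_stim`, `params_label`, `dt`.
#' @export
simulate_neuron <- function(params, I_stim, duration = 1500, dt = 0.025,
                            method = c("lsoda", "rk4"),
                            init = initial_state(params),
                            rtol = 1e-8, atol = 1e-10, keep_every = 1L) {
  method <- match.arg(method)
  stopifnot(duration > 0, dt > 0, length(init) == 4)
  p <- pack_params(params, I_stim)
  if (method == "lsoda") {
    times <- seq(0, duration, by = dt)
    out <- deSolve::lsoda(y = unname(init), times = times,
                          func = "hh_derivs", parms = p,
                          dllname = "nav11dyn", initfunc = "hh_initmod",
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (!is.finite(out[nrow(out), 2]))
      stop("integration produced a non-finite membrane potential")
    df <- data.frame(time = out[, 1], V = out[, 2], m = out[, 3],
                     h = out[, 4], n = out[, 5])
  } else {
    nsteps <- ceiling(duration / dt)
    mat <- .Call(C_hh_rk4, as.numeric(init), p, dt, as.numeric(nsteps),
                 as.integer(keep_every))
    df <- data.frame(time = seq(0, by = dt * keep_every, length.out = nrow(mat)),
                     V = mat[, 1], m = mat[, 2], h = mat[, 3], n = mat[, 4])
  }
  structure(df, class = c("sim_result", "data.frame"),
            I_stim = I_stim, params_label = params$label, dt = dt,
            method = method)
}

#' Detect action potentials in a simulated trace
#'
#' Spikes are upward crossings of a voltage threshold separated by at
#' least a refractory interval.  The firing rate is computed over the
#' analysis window after discarding an initial transient.  The trace is
#' classified as depolarisation-blocked when no spike occurs in the
#' window while the mean potential stays above `block_v` (a blocked
#' neuron sits at a depolarised plateau; a silent resting neuron does
#' not).
#'
#' @param sim A `sim_result` from [simulate_neuron()].
#' @param threshold Spike detection threshold (mV).
#' @param refractory Minimum inter-spike interval (ms).
#' @param discard_frac Fraction of the run discarded as transient.
#' @param block_v Plateau threshold for the blocked classification (mV).
#' @return An object of class `spike_train`: `spike_times` (ms), `rate`
#'   (Hz), `blocked`, `window` (ms), `mean_V`, `amplitude` (max V in the
#'   window, mV).
#' @export
detect_spikes <- function(sim, threshold = 0, refractory = 1,
                          discard_frac = 0.2, block_v = -55) {
  stopifnot(inherits(sim, "sim_result"))
  t0 <- max(sim$time) * discard_frac
  keep <- sim$time >= t0
  t <- sim$time[keep]; V <- sim$V[keep]
  up <- which(V[-length(V)] < threshold & V[-1] >= threshold) + 1
  st <- t[up]
  if (length(st) > 1) {
    acc <- st[1]
    for (k in 2:length(st))
      if (st[k] - acc[length(acc)] >= refractory) acc <- c(acc, st[k])
    st <- acc
  }
  window <- max(t) - min(t)
  structure(list(spike_times = st,
                 rate = length(st) / window * 1000,
                 blocked = length(st) == 0 && mean(V) > block_v,
                 window = window, mean_V = mean(V), amplitude = max(V)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d spikes, %.1f Hz over %.0f ms%s\n",
              length(x$spike_times), x$rate, x$window,
              if (x$blocked) " [depolarisation block]" else ""))
  invisible(x)
}

#' Firing rate versus stimulus current (f-I curve)
#'
#' Runs a continuation sweep over an increasing stimulus grid: each
#' stimulus starts from the previous one's final state.  Spike counts are
#' taken over the analysis window after a settle period, using the
#' compiled fixed-step engine.
#'
#' @param params A [neuron_params()].
#' @param I_grid Increasing stimulus values.
#' @param settle Settle time per stimulus before counting (ms).
#' @param window Analysis window per stimulus (ms).
#' @param dt Integration step (ms).
#' @param threshold,refractory Spike detection settings.
#' @return data.frame with columns `I`, `rate` (Hz), `n_spikes`, `v_min`,
#'   `v_max`.
#' @export
fi_curve <- function(params, I_grid, settle = 300, window = 500,
                     dt = 0.005, threshold = 0, refractory = 1) {
  stopifnot(all(diff(I_grid) > 0))
  res <- .Call(C_hh_sweep, as.numeric(initial_state(params)),
               pack_params(params, 0), as.numeric(I_grid),
               as.numeric(settle), as.numeric(window), as.numeric(dt),
               as.numeric(threshold), as.numeric(refractory))
  s <- res[[1]]
  if (any(s[, 4] == 0)) warning("integration failed at some stimulus values")
  data.frame(I = I_grid, rate = s[, 3] / window * 1000,
             n_spikes = s[, 3], v_min = s[, 1], v_max = s[, 2])
}
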