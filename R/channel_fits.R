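#' Evaluate a Boltzmann sigmoid
#'
#' \eqn{x(V) = 1/(1 + \exp(-(V - V_{1/2})/s))}.
#'
#' @param V Voltage(s), mV.
#' @param params A [boltzmann_params()].
#' @return Fractions in (0, 1), monotone increasing iff `slope > 0`.
#' @export
boltzmann_value <- function(V, params) {
  stopifnot(inherits(params, "boltzmann_params"))
  1 / (1 + exp(-(V - params$v_half) / params$slope))
}

# centred running mean (width w samples, edges padded by replication);
# stands in for the acquisition low-pass when hunting peaks in noise
smooth_trace <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  padded <- c(rep(x[1], w), x, rep(x[n], w))
  k <- rep(1 / w, w)
  sm <- stats::filter(padded, k, sides = 2)
  as.numeric(sm[(w + 1):(w + n)])
}

#' Signed peak currents of an activation sweep set
#'
#' Returns, per sweep, the sample of largest absolute current with its
#' sign preserved.  The first `blank_ms` of each sweep (the capacitive
#' blanking window) is excluded from the search.  A running-mean smoothing
#' window (`smooth_ms`) can be applied before the search; on noisy sweeps
#' with little channel current this suppresses the upward bias of a
#' max-of-noise extremum, playing the role of the acquisition low-pass
#' filter.
#'
#' @param sweeps A [sweep_set()] (activation protocol).
#' @param blank_ms Blanking window at sweep start (ms).
#' @param smooth_ms Running-mean width (ms); 0 searches the raw samples.
#' @return Numeric vector, one signed peak (nA) per sweep.
#' @export
peak_currents <- function(sweeps, blank_ms = 0.2, smooth_ms = 0) {
  stopifnot(inherits(sweeps, "sweep_set"))
  first <- floor(blank_ms / sweeps$dt) + 1
  if (first > ncol(sweeps$traces))
    stop("blanking window longer than the sweep")
  tr <- sweeps$traces[, first:ncol(sweeps$traces), drop = FALSE]
  if (all(tr == 0)) stop("all-zero trace set has no defined peaks")
  w <- max(1L, round(smooth_ms / sweeps$dt))
  apply(tr, 1, function(x) {
    s <- smooth_trace(x, w)
    s[which.max(abs(s))]
  })
}

#' Time to half-maximal current
#'
#' First time at which |I| crosses half of its peak absolute value,
#' linearly interpolated between samples.
#'
#' @param trace Current samples (nA).
#' @param dt Sample interval (ms).
#' @return Time (ms) from trace start.
#' @export
time_to_half_peak <- function(trace, dt) {
  stopifnot(is.numeric(trace), length(trace) > 1, dt > 0)
  a <- abs(trace)
  half <- max(a) / 2
  if (max(a) == 0) stop("flat trace: no peak to reference")
  k <- which(a >= half)[1]
  if (k == 1) return(0)
  frac <- (half - a[k - 1]) / (a[k] - a[k - 1])
  ((k - 2) + frac) * dt
}

#' Estimate the reversal potential from a peak current-voltage relation
#'
#' Linear interpolation of the zero crossing of peak current against step
#' voltage, searched on the depolarised (descending-magnitude) limb.
#'
#' @param peaks Signed peak currents (nA).
#' @param voltages Step voltages (mV), same length.
#' @return Reversal potential (mV), or `NA` if the relation never crosses
#'   zero.
#' @export
estimate_reversal <- function(peaks, voltages) {
  stopifnot(length(peaks) == length(voltages))
  imax <- which.max(abs(peaks))
  if (imax == length(peaks)) return(NA_real_)
  for (k in seq(imax, length(peaks) - 1)) {
    if (peaks[k] == 0) return(voltages[k])
    if (peaks[k] * peaks[k + 1] < 0) {
      w <- peaks[k] / (peaks[k] - peaks[k + 1])
      return(voltages[k] + w * (voltages[k + 1] - voltages[k]))
    }
  }
  if (peaks[length(peaks)] == 0) return(voltages[length(peaks)])
  NA_real_
}

#' Conductance-voltage relation from peak currents
#'
#' Ohmic conversion \eqn{G(V) = I_{peak}/(V - V_{rev})}, normalised to a
#' maximum of 1.  Voltages within `exclude_tol` of the reversal potential
#' are dropped (the driving force vanishes there), with a warning.
#'
#' @param peaks Signed peak currents (nA).
#' @param voltages Step voltages (mV).
#' @param v_rev Reversal potential (mV).
#' @param exclude_tol Exclusion half-width around `v_rev` (mV).
#' @return data.frame with columns `voltage`, `G`, `G_norm`.
#' @export
conductance_curve <- function(peaks, voltages, v_rev, exclude_tol = 2) {
  stopifnot(length(peaks) == length(voltages), is.finite(v_rev))
  keep <- abs(voltages - v_rev) > exclude_tol
  if (!all(keep))
    warning(sprintf("dropping %d point(s) within %g mV of the reversal potential",
                    sum(!keep), exclude_tol))
  if (!any(keep)) stop("all points excluded around the reversal potential")
  v <- voltages[keep]
  G <- peaks[keep] / (v - v_rev)
  data.frame(voltage = v, G = G, G_norm = G / max(G))
}

#' Fit a Boltzmann sigmoid by least squares
#'
#' Levenberg-Marquardt least squares of
#' \eqn{y = 1/(1 + \exp(-(x - V_{1/2})/s))} with the slope sign
#' constrained by `direction` (fitted on a log scale).
#'
#' @param x Voltages (mV), at least 4 points spanning the transition.
#' @param y Fractions.
#' @param direction `"rising"` (slope > 0) or `"falling"` (slope < 0).
#' @param amplitude `"fixed"` fits a unit-amplitude sigmoid; `"free"` also
#'   estimates the amplitude, which removes the bias introduced by
#'   normalising noisy data to their largest point.
#' @return A [boltzmann_params()] with attributes `rss` (residual sum of
#'   squares), `fitted` (fitted values) and `amplitude` (estimated, or 1).
#' @export
fit_boltzmann <- function(x, y, direction = c("rising", "falling"),
                          amplitude = c("fixed", "free")) {
  direction <- match.arg(direction)
  amplitude <- match.arg(amplitude)
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 points for a Boltzmann fit")
  if (diff(range(y)) < 0.2)
    stop("y range below 0.2: data do not span the transition")
  sgn <- if (direction == "rising") 1 else -1
  # start at the half-maximum crossing; slope scale from the 25-75% span
  yy <- if (direction == "rising") y else 1 - y
  v0 <- x[which.min(abs(yy - 0.5))]
  s0 <- max(abs(diff(range(x))) / 10, 1)
  df <- data.frame(x = x, y = y)
  ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)
  if (amplitude == "fixed") {
    fit <- minpack.lm::nlsLM(
      y ~ 1 / (1 + exp(-(x - vh) / (sgn * exp(ls)))),
      data = df, start = list(vh = v0, ls = log(s0)), control = ctl)
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ A / (1 + exp(-(x - vh) / (sgn * exp(ls)))),
      data = df, start = list(vh = v0, ls = log(s0), A = max(yy)),
      control = ctl)
  }
  co <- stats::coef(fit)
  out <- boltzmann_params(unname(co["vh"]), sgn * exp(unname(co["ls"])))
  attr(out, "rss") <- sum(stats::residuals(fit)^2)
  attr(out, "fitted") <- stats::fitted(fit)
  attr(out, "amplitude") <- if (amplitude == "free") unname(co["A"]) else 1
  out
}

#' Fit the full activation stage of a sweep set
#'
#' Extracts signed peaks, estimates the reversal potential from the zero
#' crossing of the peak I-V relation (falling back to the synthetic
#' ground-truth value when no crossing exists), converts to conductance,
#' and fits a rising Boltzmann.
#'
#' @param sweeps A [sweep_set()] under the activation protocol.
#' @param blank_ms Capacitive blanking window (ms).
#' @param exclude_tol Exclusion half-width around the reversal (mV).
#' @param smooth_ms Running-mean width for peak search (ms); the default
#'   emulates the acquisition low-pass filter.
#' @return An object of class `activation_fit`: list with `v_rev`,
#'   `peak_currents`, `curve` (the [conductance_curve()] frame) and
#'   `boltzmann`.
#' @export
fit_activation <- function(sweeps, blank_ms = 0.2, exclude_tol = 2,
                           smooth_ms = 0.25) {
  stopifnot(inherits(sweeps, "sweep_set"),
            sweeps$protocol$kind == "activation")
  volts <- sweeps$protocol$step_voltages
  peaks <- peak_currents(sweeps, blank_ms, smooth_ms)
  v_rev <- estimate_reversal(peaks, volts)
  if (is.na(v_rev)) {
    if (is.null(sweeps$ground_truth))
      stop("peak I-V has no zero crossing and no ground-truth reversal is available")
    v_rev <- sweeps$ground_truth$e_rev
  }
  curve <- conductance_curve(peaks, volts, v_rev, exclude_tol)
  bz <- fit_boltzmann(curve$voltage, curve$G_norm, "rising",
                      amplitude = "free")
  structure(list(v_rev = v_rev, peak_currents = peaks, curve = curve,
                 boltzmann = bz),
            class = "activation_fit")
}

#' Fit steady-state fast inactivation (availability) of a sweep set
#'
#' Measures the peak current in the test-pulse window of each sweep,
#' normalises by the largest across prepulse voltages, and fits a falling
#' Boltzmann against prepulse voltage.
#'
#' @param sweeps A [sweep_set()] under the ssfi protocol.
#' @param blank_ms Blanking window after the test-pulse onset (ms).
#' @param smooth_ms Running-mean width for peak search (ms).
#' @return An object of class `inactivation_fit`: list with
#'   `normalized_I`, `voltages`, `boltzmann`.
#' @export
fit_ssfi <- function(sweeps, blank_ms = 0.2, smooth_ms = 0.25) {
  stopifnot(inherits(sweeps, "sweep_set"), sweeps$protocol$kind == "ssfi")
  pro <- sweeps$protocol
  t <- sweep_times(sweeps)
  win <- t >= pro$prepulse_duration + blank_ms
  if (!any(win)) stop("no samples in the test-pulse window")
  w <- max(1L, round(smooth_ms / sweeps$dt))
  peaks <- apply(sweeps$traces[, win, drop = FALSE], 1,
                 function(x) max(abs(smooth_trace(x, w))))
  norm <- peaks / max(peaks)
  bz <- fit_boltzmann(pro$step_voltages, norm, "falling")
  structure(list(normalized_I = norm, voltages = pro$step_voltages,
                 boltzmann = bz),
            class = "inactivation_fit")
}

#' Fit a single-exponential decay to the open-state inactivation phase
#'
#' Fits \eqn{I(t) = A e^{-t/\tau} + c} from the segment start (the peak)
#' to the segment end.
#'
#' @param trace Current segment starting at the peak (nA).
#' @param dt Sample interval (ms).
#' @param voltage Step voltage (mV), carried on the result.
#' @return An object of class `decay_fit`: list with `voltage`, `tau`
#'   (ms), `A`, `offset`.
#' @export
fit_single_exp_decay <- function(trace, dt, voltage = NA_real_) {
  stopifnot(is.numeric(trace), length(trace) >= 5, dt > 0)
  a <- abs(trace)
  if (which.max(a) != 1)
    stop("segment must start at its peak (decaying from the first sample)")
  if (a[length(a)] >= a[1])
    stop("segment does not decay")
  t <- (seq_along(trace) - 1) * dt
  A0 <- trace[1] - trace[length(trace)]
  # crude tau start: time to reach 1/e of the initial excess
  k <- which(a - a[length(a)] <= (a[1] - a[length(a)]) / exp(1))[1]
  tau0 <- max(t[k], dt)
  df <- data.frame(t = t, y = trace)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-t / exp(ltau)) + c0, data = df,
                           start = list(A = A0, ltau = log(tau0),
                                        c0 = trace[length(trace)]),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  structure(list(voltage = voltage, tau = exp(unname(co["ltau"])),
                 A = unname(co["A"]), offset = unname(co["c0"])),
            class = "decay_fit")
}

#' Fit open-state inactivation time constants across activation sweeps
#'
#' For each requested step voltage, extracts the decay segment (from the
#' peak to the end of the step) and fits a single exponential.
#'
#' @param sweeps Activation [sweep_set()].
#' @param voltages Step voltages to analyse (default: -10 mV and above,
#'   where the decay is well defined).
#' @param blank_ms Capacitive blanking window (ms).
#' @return data.frame with columns `voltage`, `tau`.
#' @export
fit_decay_curve <- function(sweeps, voltages = NULL, blank_ms = 0.2) {
  stopifnot(inherits(sweeps, "sweep_set"),
            sweeps$protocol$kind == "activation")
  sv <- sweeps$protocol$step_voltages
  if (is.null(voltages)) voltages <- sv[sv >= -10]
  first <- floor(blank_ms / sweeps$dt) + 1
  out <- lapply(voltages, function(v) {
    i <- which(sv == v)
    if (length(i) != 1) stop(sprintf("voltage %g not in protocol", v))
    tr <- sweeps$traces[i, first:ncol(sweeps$traces)]
    pk <- which.max(abs(tr))
    fit_single_exp_decay(tr[pk:length(tr)], sweeps$dt, voltage = v)
  })
  data.frame(voltage = voltages,
             tau = vapply(out, function(f) f$tau, numeric(1)))
}

#' Fit a double-exponential recovery time course
#'
#' Fits \eqn{y(t) = c + A_f (1 - e^{-t/\tau_f}) + A_s (1 - e^{-t/\tau_s})}
#' to recovered fractions against recovery time, with multi-start
#' Levenberg-Marquardt.  Time constants are reported sorted
#' (`tau_fast < tau_slow`).  When the two components are not separable
#' (effectively single-exponential data) the best single-exponential fit
#' is returned with `fallback_single = TRUE`.
#'
#' @param fractions Recovered fractions (test/conditioning peak ratio).
#' @param recovery_times Recovery intervals (ms), >= 6 points.
#' @return An object of class `recovery_fit`: `tau_fast`, `tau_slow`,
#'   `A_fast`, `A_slow`, `offset`, `fallback_single`, `rss`.
#' @export
fit_recovery_curve <- function(fractions, recovery_times) {
  stopifnot(length(fractions) == length(recovery_times))
  if (length(fractions) < 6) stop("need at least 6 recovery time points")
  t <- recovery_times
  df <- data.frame(t = t, y = fractions)
  span <- max(fractions) - min(fractions)
  tmid <- stats::median(t)
  starts <- list(
    list(Af = 0.6 * span, As = 0.4 * span, lf = log(tmid / 10), ls = log(tmid * 2)),
    list(Af = 0.8 * span, As = 0.2 * span, lf = log(tmid / 30), ls = log(tmid)),
    list(Af = 0.4 * span, As = 0.6 * span, lf = log(tmid / 3),  ls = log(tmid * 5))
  )
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c0 + Af * (1 - exp(-t / exp(lf))) + As * (1 - exp(-t / exp(ls))),
        data = df,
        start = c(s0, c0 = min(fractions)),
        lower = c(0, 0, -Inf, -Inf, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < attr(best, "rss_")) {
        attr(fit, "rss_") <- rss
        best <- fit
      }
    }
  }
  single <- tryCatch(
    minpack.lm::nlsLM(y ~ c0 + A * (1 - exp(-t / exp(lt))), data = df,
                      start = list(A = span, lt = log(tmid), c0 = min(fractions)),
                      lower = c(0, -Inf, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  use_single <- FALSE
  if (is.null(best)) {
    use_single <- TRUE
  } else {
    co <- stats::coef(best)
    taus <- sort(exp(c(unname(co["lf"]), unname(co["ls"]))))
    amps <- c(unname(co["Af"]), unname(co["As"]))
    # degenerate double fits: indistinguishable time constants or a
    # vanishing component mean the data are effectively single-exponential
    if (taus[2] / taus[1] < 1.5 || min(amps) < 1e-3 * max(sum(amps), 1)) {
      if (!is.null(single) &&
          sum(stats::residuals(single)^2) < 2 * attr(best, "rss_"))
        use_single <- TRUE
    }
  }
  if (use_single) {
    if (is.null(single)) stop("recovery fit failed to converge")
    co <- stats::coef(single)
    tau <- exp(unname(co["lt"]))
    return(structure(list(tau_fast = tau, tau_slow = tau,
                          A_fast = unname(co["A"]), A_slow = 0,
                          offset = unname(co["c0"]),
                          fallback_single = TRUE,
                          rss = sum(stats::residuals(single)^2)),
                     class = "recovery_fit"))
  }
  co <- stats::coef(best)
  tf <- exp(unname(co["lf"])); ts <- exp(unname(co["ls"]))
  Af <- unname(co["Af"]); As <- unname(co["As"])
  if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp; tmp <- Af; Af <- As; As <- tmp }
  structure(list(tau_fast = tf, tau_slow = ts, A_fast = Af, A_slow = As,
                 offset = unname(co["c0"]), fallback_single = FALSE,
                 rss = attr(best, "rss_")),
            class = "recovery_fit")
}

#' Recovered fractions and double-exponential fit from a recovery sweep set
#'
#' The recovered fraction at each recovery time is the peak test-pulse
#' current divided by the peak conditioning-pulse current of the same
#' sweep.
#'
#' @param sweeps A [sweep_set()] under the recovery protocol.
#' @param blank_ms Blanking window after each pulse onset (ms).
#' @param smooth_ms Running-mean width for peak search (ms).
#' @return A `recovery_fit` (see [fit_recovery_curve()]) with the
#'   measured `fractions` and `recovery_times` attached.
#' @export
fit_recovery <- function(sweeps, blank_ms = 0.2, smooth_ms = 0.25) {
  stopifnot(inherits(sweeps, "sweep_set"),
            sweeps$protocol$kind == "recovery")
  pro <- sweeps$protocol
  t <- sweep_times(sweeps)
  w <- max(1L, round(smooth_ms / sweeps$dt))
  cond_win <- t >= blank_ms & t < pro$conditioning_duration
  fractions <- vapply(seq_along(pro$recovery_times), function(i) {
    rt <- pro$recovery_times[i]
    t0 <- pro$conditioning_duration + rt
    test_win <- t >= t0 + blank_ms & t < t0 + pro$step_duration
    pk_cond <- max(abs(smooth_trace(sweeps$traces[i, cond_win], w)))
    pk_test <- max(abs(smooth_trace(sweeps$traces[i, test_win], w)))
    pk_test / pk_cond
  }, numeric(1))
  fit <- fit_recovery_curve(fractions, pro$recovery_times)
  fit$fractions <- fractions
  fit$recovery_times <- pro$recovery_times
  fit
}
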