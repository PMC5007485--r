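#' Continuation sweep of steady-window voltage extrema over a stimulus grid
#'
#' Integrates the model along an increasing (`"up"`) or decreasing
#' (`"down"`) stimulus grid; each grid point continues from the previous
#' one's final state, a settle period is discarded, and the voltage
#' extrema over the analysis window are recorded.  A grid point is
#' classified as oscillating when its peak-to-peak voltage span exceeds
#' `amp_threshold`.
#'
#' @param params A [neuron_params()].
#' @param I_grid Increasing stimulus grid (traversed in reverse for the
#'   down sweep).
#' @param direction `"up"` or `"down"`.
#' @param settle Settle time per grid point (ms).
#' @param window Analysis window per grid point (ms).
#' @param dt Integration step (ms).
#' @param amp_threshold Peak-to-peak span (mV) above which the window
#'   counts as oscillating.
#' @param init Initial state for the first grid point.
#' @return data.frame in increasing-I order: `I`, `v_min`, `v_max`,
#'   `n_spikes`, `oscillating`, `ok` (FALSE after an integration
#'   failure); attribute `direction`.
#' @export
bifurcation_sweep <- function(params, I_grid, direction = c("up", "down"),
                              settle = 500, window = 500, dt = 0.005,
                              amp_threshold = 10,
                              init = initial_state(params)) {
  direction <- match.arg(direction)
  stopifnot(all(diff(I_grid) > 0))
  grid <- if (direction == "up") I_grid else rev(I_grid)
  res <- .Call(C_hh_sweep, as.numeric(init), pack_params(params, 0),
               as.numeric(grid), as.numeric(settle), as.numeric(window),
               as.numeric(dt), 0, 1)
  s <- res[[1]]
  if (direction == "down") s <- s[nrow(s):1, , drop = FALSE]
  out <- data.frame(I = I_grid, v_min = s[, 1], v_max = s[, 2],
                    n_spikes = s[, 3],
                    oscillating = (s[, 2] - s[, 1]) > amp_threshold,
                    ok = s[, 4] == 1)
  if (any(!out$ok)) warning("integration failed at some grid points")
  attr(out, "direction") <- direction
  out
}

# largest oscillating I (offset) and smallest oscillating I (onset)
mask_bounds <- function(I, mask) {
  if (!any(mask)) return(c(onset = NA_real_, offset = NA_real_))
  c(onset = min(I[mask]), offset = max(I[mask]))
}

#' Classify a pair of up/down sweeps into a bifurcation diagram
#'
#' Combines the two sweep directions: extracts oscillation onset and
#' offset currents per direction and flags bistability when, near the
#' oscillation offset, the two directions disagree (one oscillates where
#' the other rests) over more than one grid step - the signature of
#' coexisting resting and spiking attractors (hysteresis).
#'
#' @param up,down Sweeps from [bifurcation_sweep()] on the same grid.
#' @return An object of class `bifurcation_diagram`: `I_grid`, the two
#'   sweeps, `onset_up`, `offset_up`, `onset_down`, `offset_down`,
#'   `bistable`, `bistable_interval` (numeric range or NULL),
#'   `bistable_width`, `grid_step`.
#' @export
classify_bifurcation <- function(up, down) {
  stopifnot(is.data.frame(up), is.data.frame(down))
  if (nrow(up) != nrow(down) || any(up$I != down$I))
    stop("up and down sweeps must share an identical stimulus grid")
  I <- up$I
  step <- stats::median(diff(I))
  bu <- mask_bounds(I, up$oscillating)
  bd <- mask_bounds(I, down$oscillating)
  disagree <- up$oscillating != down$oscillating
  # contiguous runs of disagreement; bistable iff one spans > 1 grid step
  r <- rle(disagree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths > 1)
  bist <- length(runs) > 0
  interval <- NULL
  width <- 0
  if (bist) {
    k <- runs[which.max(r$lengths[runs])]
    interval <- c(I[starts[k]], I[ends[k]])
    width <- diff(interval)
  }
  structure(list(I_grid = I, up = up, down = down,
                 onset_up = bu["onset"], offset_up = bu["offset"],
                 onset_down = bd["onset"], offset_down = bd["offset"],
                 bistable = bist, bistable_interval = interval,
                 bistable_width = width, grid_step = step),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("bifurcation_diagram: offset(up) = %.4g, offset(down) = %.4g\n",
              x$offset_up, x$offset_down))
  if (x$bistable)
    cat(sprintf("  bistable over [%.4g, %.4g] (width %.4g)\n",
                x$bistable_interval[1], x$bistable_interval[2],
                x$bistable_width))
  else cat("  monostable (no hysteresis beyond one grid step)\n")
  invisible(x)
}

#' Up/down bifurcation diagram for one condition
#'
#' Convenience wrapper: runs [bifurcation_sweep()] in both directions and
#' classifies the result.  The down sweep starts from the up sweep's
#' final (high-stimulus) state so that it descends from the blocked
#' branch.
#'
#' @inheritParams bifurcation_sweep
#' @return A `bifurcation_diagram` (see [classify_bifurcation()]).
#' @export
bifurcation_diagram <- function(params, I_grid = seq(0, 80, by = 0.25),
                                settle = 500, window = 500, dt = 0.005,
                                amp_threshold = 10) {
  up <- bifurcation_sweep(params, I_grid, "up", settle, window, dt,
                          amp_threshold)
  # the down sweep's first grid point (highest I) settles onto the
  # high-stimulus attractor before descending
  down <- bifurcation_sweep(params, I_grid, "down", settle, window, dt,
                            amp_threshold)
  classify_bifurcation(up, down)
}

#' Compare oscillation-offset currents and bistability across conditions
#'
#' Reports the offset-current ordering over a set of condition diagrams
#' and evaluates the qualitative claims of interest: the mutant at 40 C
#' has the largest oscillation offset; each mutant condition exceeds its
#' wild-type counterpart; and the bistable-interval width shrinks across
#' WT37, WT40, AV37, AV40.  Offsets within one grid step of each other
#' are flagged as ties rather than silently ordered.
#'
#' @param diagrams Named list of `bifurcation_diagram` objects on a
#'   shared grid (names are condition labels).
#' @return An object of class `condition_comparison`: data.frame
#'   `summary` (label, offset_up, offset_down, bistable, bistable_width),
#'   `max_offset_label`, `ties` (labels within one grid step of the
#'   maximum), and logical claim fields `av40_is_max`,
#'   `av37_gt_wt37`, `av40_gt_wt40`, `width_nonincreasing`.
#' @export
compare_conditions <- function(diagrams) {
  stopifnot(is.list(diagrams), length(diagrams) >= 2,
            !is.null(names(diagrams)))
  g1 <- diagrams[[1]]$I_grid
  for (d in diagrams)
    if (length(d$I_grid) != length(g1) || any(d$I_grid != g1))
      stop("all diagrams must share the same stimulus grid")
  step <- diagrams[[1]]$grid_step
  summ <- data.frame(
    label = names(diagrams),
    offset_up = vapply(diagrams, function(d) unname(d$offset_up), numeric(1)),
    offset_down = vapply(diagrams, function(d) unname(d$offset_down), numeric(1)),
    bistable = vapply(diagrams, function(d) d$bistable, logical(1)),
    bistable_width = vapply(diagrams, function(d) d$bistable_width, numeric(1)),
    row.names = NULL)
  imax <- which.max(summ$offset_up)
  ties <- summ$label[abs(summ$offset_up - summ$offset_up[imax]) <= step &
                       seq_len(nrow(summ)) != imax]
  has <- function(l) l %in% summ$label
  off <- function(l) summ$offset_up[summ$label == l]
  claims <- list(av40_is_max = NA, av37_gt_wt37 = NA, av40_gt_wt40 = NA,
                 width_nonincreasing = NA)
  if (all(vapply(c("WT37", "WT40", "AV37", "AV40"), has, logical(1)))) {
    claims$av40_is_max <- summ$label[imax] == "AV40" && length(ties) == 0
    claims$av37_gt_wt37 <- off("AV37") > off("WT37")
    claims$av40_gt_wt40 <- off("AV40") > off("WT40")
    w <- vapply(c("WT37", "WT40", "AV37", "AV40"),
                function(l) summ$bistable_width[summ$label == l], numeric(1))
    claims$width_nonincreasing <- all(diff(w) <= 0)
  }
  structure(c(list(summary = summ, max_offset_label = summ$label[imax],
                   ties = ties, grid_step = step), claims),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Oscillation-offset comparison across conditions\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("max offset: %s%s\n", x$max_offset_label,
              if (length(x$ties)) paste0(" (tied with ",
                                         paste(x$ties, collapse = ", "),
                                         " within one grid step)") else ""))
  invisible(x)
}
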