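#' Configuration for a full desk-scale study run
#'
#' @param seed Integer seed controlling all synthetic-data noise.
#' @param noise_sd Noise SD for the voltage-clamp generator (nA); `NULL`
#'   uses 1% of peak current.
#' @param I_low,I_high Low/high stimulus values for the single-run stage.
#' @param I_grid Stimulus grid for f-I and bifurcation sweeps.
#' @param duration Single-run duration (ms).
#' @param settle,window Bifurcation sweep settle and analysis windows (ms).
#' @param dt Integration step (ms) for the fixed-step stages.
#' @param conditions Condition labels to run.
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, noise_sd = NULL, I_low = 0.2, I_high = 45,
                       I_grid = seq(0, 80, by = 0.5), duration = 1500,
                       settle = 500, window = 500, dt = 0.005,
                       conditions = condition_labels(), out_dir = NULL) {
  structure(list(seed = seed, noise_sd = noise_sd, I_low = I_low,
                 I_high = I_high, I_grid = I_grid, duration = duration,
                 settle = settle, window = window, dt = dt,
                 conditions = conditions, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline at desk scale
#'
#' Synthesises voltage-clamp data and recovers the gating parameters,
#' rebuilds the four condition parameterisations from deltas, simulates
#' the low- and high-input responses, and runs the bifurcation
#' comparison.  When `config$out_dir` is set, per-stage JSON/CSV
#' artifacts are written there.
#'
#' @param config A [run_config()].
#' @return A report list with elements `channel_fits` (truth vs fitted
#'   Boltzmann midpoints), `conditions` (the four parameter rows),
#'   `firing` (per condition x stimulus: rate, blocked, amplitude) and
#'   `bifurcation` (a [compare_conditions()] result), plus the `config`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  pro <- default_protocols()
  truth <- true_channel_params(noise_sd = config$noise_sd)

  act <- generate_sweepset(truth, pro$activation, seed = config$seed)
  ina <- generate_sweepset(truth, pro$ssfi, seed = config$seed + 1)
  rec <- generate_sweepset(truth, pro$recovery, seed = config$seed + 2)
  fa <- fit_activation(act)
  fs <- fit_ssfi(ina)
  fr <- fit_recovery(rec)
  channel_fits <- data.frame(
    quantity = c("activation_v_half", "activation_slope",
                 "ssfi_v_half", "ssfi_slope",
                 "recovery_tau_fast", "recovery_tau_slow"),
    truth = c(truth$m_gate$v_half, truth$m_gate$slope,
              truth$h_gate$v_half, truth$h_gate$slope, NA, NA),
    fitted = c(fa$boltzmann$v_half, fa$boltzmann$slope,
               fs$boltzmann$v_half, fs$boltzmann$slope,
               fr$tau_fast, fr$tau_slow))

  base <- load_condition("WT37")
  deltas <- table1_deltas()
  conds <- lapply(config$conditions, function(l)
    apply_deltas(base, deltas[[l]], label = l))
  names(conds) <- config$conditions

  firing <- do.call(rbind, lapply(config$conditions, function(l) {
    do.call(rbind, lapply(c(low = config$I_low, high = config$I_high),
                          function(I) {
      sim <- simulate_neuron(conds[[l]], I, duration = config$duration,
                             dt = config$dt, method = "rk4",
                             keep_every = 5L)
      sp <- detect_spikes(sim)
      data.frame(label = l, I_stim = I, rate = sp$rate,
                 n_spikes = length(sp$spike_times),
                 blocked = sp$blocked, amplitude = sp$amplitude)
    }))
  }))
  rownames(firing) <- NULL

  diagrams <- lapply(conds, function(p)
    bifurcation_diagram(p, config$I_grid, settle = config$settle,
                        window = config$window, dt = config$dt))
  comparison <- compare_conditions(diagrams)

  report <- list(config = config, channel_fits = channel_fits,
                 conditions = conds, firing = firing,
                 bifurcation = comparison)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(config$out_dir, ...)
    write_sweepset(act, p("activation_traces.csv"), p("activation_meta.json"))
    utils::write.csv(channel_fits, p("channel_fits.csv"), row.names = FALSE)
    for (l in names(conds)) write_condition(conds[[l]], p(paste0(l, ".json")))
    utils::write.csv(firing, p("firing.csv"), row.names = FALSE)
    utils::write.csv(comparison$summary, p("bifurcation_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = config$seed,
                              I_low = config$I_low, I_high = config$I_high,
                              dt = config$dt,
                              grid = range(config$I_grid)),
                         p("run_config.json"), auto_unbox = TRUE)
  }
  report
}
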