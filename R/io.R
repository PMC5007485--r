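#' @importFrom utils read.csv write.csv
NULL

truth_to_list <- function(gt) {
  if (is.null(gt)) return(NULL)
  list(g_max = gt$g_max, e_rev = gt$e_rev,
       m_gate = list(v_half = gt$m_gate$v_half, slope = gt$m_gate$slope),
       h_gate = list(v_half = gt$h_gate$v_half, slope = gt$h_gate$slope),
       tau_m_base = gt$tau_m_base, tau_m_floor = gt$tau_m_floor,
       tau_h_base = gt$tau_h_base, tau_h_floor = gt$tau_h_floor,
       noise_sd = gt$noise_sd)
}

truth_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  true_channel_params(g_max = x$g_max, e_rev = x$e_rev,
                      m_gate = boltzmann_params(x$m_gate$v_half, x$m_gate$slope),
                      h_gate = boltzmann_params(x$h_gate$v_half, x$h_gate$slope),
                      tau_m_base = x$tau_m_base, tau_m_floor = x$tau_m_floor,
                      tau_h_base = x$tau_h_base, tau_h_floor = x$tau_h_floor,
                      noise_sd = x$noise_sd)
}

protocol_to_list <- function(p) {
  keep <- !vapply(unclass(p), is.null, logical(1))
  unclass(p)[keep]
}

protocol_from_list <- function(x) {
  # JSON parsing yields integers for whole numbers; protocols are numeric
  x[names(x) != "kind"] <- lapply(x[names(x) != "kind"], as.numeric)
  do.call(voltage_protocol, x)
}

#' Write a sweep set to disk
#'
#' Traces go to a CSV with a `time_ms` column followed by one column per
#' sweep (`sweep_000`, `sweep_001`, ...); protocol, temperature, condition,
#' units and optional ground truth go to a JSON metadata file.  The pair
#' round-trips losslessly through [read_sweepset()].
#'
#' @param sweeps A [sweep_set()].
#' @param path_traces,path_meta Output file paths (CSV, JSON).
#' @return Invisibly, `c(path_traces, path_meta)`.
#' @export
write_sweepset <- function(sweeps, path_traces, path_meta) {
  stopifnot(inherits(sweeps, "sweep_set"))
  tr <- t(sweeps$traces)
  colnames(tr) <- sprintf("sweep_%03d", seq_len(nrow(sweeps$traces)) - 1)
  df <- data.frame(time_ms = sweep_times(sweeps), tr, check.names = FALSE)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path_traces, row.names = FALSE, quote = FALSE)
  meta <- list(protocol = protocol_to_list(sweeps$protocol),
               temperature_C = sweeps$temperature,
               condition = sweeps$condition_label,
               units = list(time = "ms", current = "nA", voltage = "mV"),
               ground_truth = truth_to_list(sweeps$ground_truth))
  jsonlite::write_json(meta, path_meta, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(path_traces, path_meta))
}

#' Read a sweep set from disk
#'
#' Counterpart of [write_sweepset()].  The trace file must have a strictly
#' increasing, evenly spaced `time_ms` first column and one column per
#' sweep; the sweep count must match the protocol in the metadata.
#'
#' @param path_traces,path_meta File paths written by [write_sweepset()].
#' @return A validated [sweep_set()].
#' @export
read_sweepset <- function(path_traces, path_meta) {
  df <- read.csv(path_traces, check.names = FALSE)
  if (!"time_ms" %in% names(df))
    stop("trace file is missing the 'time_ms' column")
  tm <- df$time_ms
  if (length(tm) < 2 || any(diff(tm) <= 0))
    stop("'time_ms' must be strictly increasing")
  dts <- diff(tm)
  if (max(dts) - min(dts) > 1e-6 * max(dts))
    stop("'time_ms' must be evenly spaced")
  meta <- jsonlite::read_json(path_meta, simplifyVector = TRUE)
  protocol <- protocol_from_list(meta$protocol)
  traces <- t(as.matrix(df[setdiff(names(df), "time_ms")]))
  if (nrow(traces) != n_sweeps(protocol))
    stop(sprintf("metadata protocol implies %d sweeps but trace file has %d",
                 n_sweeps(protocol), nrow(traces)))
  gt <- meta$ground_truth
  if (!is.null(gt) && !is.list(gt$m_gate)) gt <- lapply(gt, as.list) # simplified
  sweep_set(dt = mean(dts), traces = unname(traces), protocol = protocol,
            temperature = as.numeric(meta$temperature_C),
            condition_label = meta$condition,
            ground_truth = truth_from_list(meta$ground_truth))
}

#' Write a neuron parameterisation to a JSON config file
#'
#' Field names mirror the condition table: `C`, `gL`, `gK`, `gNa`, `EL`,
#' `EK`, `ENa`, `Vt`, `sm`, `sh`, `V2m`, `V2h`, `Toff`, plus `label`.
#' Values are written at full double precision so that presets round-trip
#' bit-identically.
#'
#' @param params A [neuron_params()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_condition <- function(params, path) {
  stopifnot(inherits(params, "neuron_params"))
  x <- list(label = params$label, C = params$C,
            gL = params$g_L, gK = params$g_K, gNa = params$g_Na,
            EL = params$E_L, EK = params$E_K, ENa = params$E_Na,
            Vt = params$V_t,
            sm = params$m_gate$slope, sh = params$h_gate$slope,
            V2m = params$m_gate$v_half, V2h = params$h_gate$v_half,
            Toff = params$T_off)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a neuron parameterisation from a JSON config file
#'
#' @param path A file written by [write_condition()].
#' @return A [neuron_params()].
#' @export
read_condition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x[names(x) != "label"] <- lapply(x[names(x) != "label"], as.numeric)
  neuron_params(C = x$C, g_L = x$gL, g_K = x$gK, g_Na = x$gNa,
                E_L = x$EL, E_K = x$EK, E_Na = x$ENa, V_t = x$Vt,
                m_gate = boltzmann_params(x$V2m, x$sm),
                h_gate = boltzmann_params(x$V2h, x$sh),
                T_off = x$Toff, label = x$label)
}
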