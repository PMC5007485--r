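# Shared fixtures: a realistic ground-truth channel and small protocols.
# All synthetic data are generated in code at test time.

default_truth <- function(noise_sd = NULL) {
  true_channel_params(noise_sd = noise_sd)
}

# closed-form h time constant of the synthetic channel at voltage V
truth_tau_h <- function(truth, V) {
  truth$tau_h_base / cosh((V - truth$h_gate$v_half) /
                            (2 * truth$h_gate$slope)) + truth$tau_h_floor
}

# printed condition table, re-entered independently for fidelity checks
# (AV40 sh stored negative: availability falls with depolarisation)
expected_table <- list(
  WT37 = c(sm = 7.4, sh = -4.0, V2m = -39.0, V2h = -43.3, Toff = 0),
  WT40 = c(sm = 6.6, sh = -3.4, V2m = -32.5, V2h = -45.2, Toff = 1.9),
  AV37 = c(sm = 6.1, sh = -3.4, V2m = -33.1, V2h = -41.0, Toff = -2.4),
  AV40 = c(sm = 7.6, sh = -3.8, V2m = -29.1, V2h = -31.6, Toff = -11.7)
)

# leak-only neuron: no voltage-gated channels, can never oscillate
leak_only_params <- function() {
  p <- load_condition("WT37")
  neuron_params(C = p$C, g_L = p$g_L, g_K = 0, g_Na = 0,
                E_L = p$E_L, E_K = p$E_K, E_Na = p$E_Na, V_t = p$V_t,
                m_gate = p$m_gate, h_gate = p$h_gate, T_off = p$T_off,
                label = "leak_only")
}

# leak + delayed-rectifier only: monotone relaxation, monostable for all I
leak_k_params <- function() {
  p <- load_condition("WT37")
  neuron_params(C = p$C, g_L = p$g_L, g_K = p$g_K, g_Na = 0,
                E_L = p$E_L, E_K = p$E_K, E_Na = p$E_Na, V_t = p$V_t,
                m_gate = p$m_gate, h_gate = p$h_gate, T_off = p$T_off,
                label = "leak_K")
}
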