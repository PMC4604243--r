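# Shared fixtures: computed once per test session.

# default membrane parameters and their absolute versions
np_default <- default_neuron_params()
cp_default <- absolute_cell_params(np_default)
cp_row <- function(type) cp_default[cp_default$cell_type == type, ]

# full calibration is used by several files; cache it
calibration_cache <- local({
  cal <- NULL
  function() {
    if (is.null(cal)) cal <<- calibrate_synapses(np_default)
    cal
  }
})

# independent fine-step ODE integration of the STP equations
# dR/dt = (1-R)/tau_rec - U R delta(t - t_sp)
# dU/dt = -U/tau_facil + U1 (1-U) delta(t - t_sp)
# (forward Euler at a step much smaller than any time constant); the
# release scale applied at each spike is U_eff * R just before depletion.
stp_ode_oracle <- function(stp, spike_times, dt = 0.01) {
  t_end <- max(spike_times) + dt
  R <- 1; u <- 0
  release <- numeric(length(spike_times))
  k_spike <- as.integer(round(spike_times / dt))
  sp_i <- 1
  facil <- stp$mode == "facilitating"
  for (k in seq_len(as.integer(round(t_end / dt)))) {
    R <- R + dt * (1 - R) / stp$tau_rec
    if (facil && stp$tau_facil > 0) u <- u - dt * u / stp$tau_facil
    while (sp_i <= length(k_spike) && k_spike[sp_i] == k) {
      if (facil) u <- u + stp$U1 * (1 - u)
      U_eff <- if (facil) u else stp$U
      release[sp_i] <- U_eff * R
      R <- R - U_eff * R
      sp_i <- sp_i + 1
    }
  }
  release
}

# tiny two-cell "network" used by engine motif tests: cell 1 -> cell 2
# through one synapse of the given class/receptor
motif_network <- function(pre_type = "PC", post_type = "MC",
                          class = "PC-MC_LO", receptor = "AMPA",
                          delay_ms = 1) {
  cells <- data.frame(id = 1:2, type = c(pre_type, post_type),
                      hc = 1L, mc = 1L, bc_orient = NA_integer_,
                      x = c(0, 100), y = 0, z = 0)
  edges <- data.frame(pre = 1L, post = 2L, class = class,
                      receptor = receptor, weight_scale = 1,
                      delay_ms = delay_ms)
  spec <- network_spec(grid = c(1, 1), seed = 1)
  structure(list(spec = spec, cells = cells, edges = edges, n_hc = 1),
            class = "column_network")
}
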