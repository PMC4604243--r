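#' Simulation configuration
#'
#' @param t_total total simulated time (s).
#' @param dt integration step (ms); 0.05 is the network default, halve it
#'   for accuracy checks.
#' @param seed integer seed for all dynamical randomness (per-cell
#'   noise/drive streams are derived from it).
#' @param record_v cell ids whose membrane potential is recorded.
#' @param record_stride record every `record_stride`-th step.
#' @param lockout spike-detection dead time (ms) after an upward crossing
#'   of 0 mV.
#' @param mg Mg2+ concentration (mM) for the NMDA block.
#' @param tau_noise correlation time (ms) of the point-conductance
#'   Ornstein-Uhlenbeck drives.
#' @param syn_stride receptor gating and the OU drives are advanced every
#'   `syn_stride` steps (conductances held in between); their time
#'   constants are well above the resulting sub-grid at the default
#'   0.2 ms. Set to 1 for exact per-step updates.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(t_total, dt = 0.05, seed = 1, record_v = integer(0),
                       record_stride = 20L, lockout = 2, mg = 1,
                       tau_noise = 2.7, syn_stride = 4L) {
  stopifnot(dt > 0, t_total > 0, syn_stride >= 1)
  structure(list(t_total = t_total, dt = dt, seed = seed,
                 record_v = as.integer(record_v),
                 record_stride = as.integer(record_stride),
                 lockout = lockout, mg = mg, tau_noise = tau_noise,
                 syn_stride = as.integer(syn_stride)),
            class = "sim_config")
}

# Resolve per-edge synapse parameters: calibrated conductance, receptor
# kinetics, STP constants (with the variant's long-range dynamics and any
# tau_facil override applied).
resolve_synapses <- function(network, calibration, dt) {
  edges <- network$edges
  if (nrow(edges) == 0) {
    return(data.frame(pre = integer(0), post = integer(0), G = numeric(0),
                      kin = integer(0), bucket = integer(0), E = numeric(0),
                      delay_steps = integer(0), stp_mode = integer(0),
                      U = numeric(0), U1 = numeric(0), tau_rec = numeric(0),
                      tau_facil = numeric(0)))
  }
  key <- paste(edges$class, edges$receptor)
  ckey <- paste(calibration$class, calibration$receptor)
  idx <- match(key, ckey)
  if (anyNA(idx))
    stop("missing calibration for class(es): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  G <- calibration$G[idx] * edges$weight_scale
  kinetics <- receptor_kinetics()
  kidx <- match(edges$receptor, kinetics$receptor)
  kin <- ifelse(kinetics$mg_block[kidx], 1L, 0L)
  bucket <- ifelse(kinetics$mg_block[kidx], 1L,
                   ifelse(kinetics$E_rev[kidx] >= -10, 0L, 2L))
  spec <- network$spec
  stp <- resolved_stp_table(spec$lr_dynamics, spec$tau_facil_override)
  sidx <- match(edges$class, stp$class)
  if (anyNA(sidx))
    stop("missing short-term plasticity parameters for: ",
         paste(unique(edges$class[is.na(sidx)]), collapse = ", "))
  data.frame(
    pre = edges$pre, post = edges$post, G = G, kin = kin, bucket = bucket,
    E = kinetics$E_rev[kidx],
    delay_steps = pmax(1L, as.integer(ceiling(edges$delay_ms / dt))),
    stp_mode = ifelse(stp$mode[sidx] == "depressing", 1L, 2L),
    U = ifelse(is.na(stp$U[sidx]), 0, stp$U[sidx]),
    U1 = ifelse(is.na(stp$U1[sidx]), 0, stp$U1[sidx]),
    tau_rec = stp$tau_rec[sidx],
    tau_facil = ifelse(is.na(stp$tau_facil[sidx]), 0, stp$tau_facil[sidx]))
}

#' Run a network simulation
#'
#' Fixed-step integration of a built network with delayed spike delivery.
#' Detected spikes (upward crossings of 0 mV, 2 ms lockout) are queued on
#' each outgoing connection with its conduction delay (rounded up to the
#' step grid); on arrival the short-term plasticity state is updated and
#' the receptor gating incremented by the release scale. The run is
#' reproducible bit-for-bit given (network, drives, config).
#'
#' @param network a `column_network` from [build_network()].
#' @param calibration conductance table from [calibrate_synapses()].
#' @param config a [sim_config()].
#' @param noise background [noise_spec()] applied to every cell; NULL
#'   disables noise.
#' @param stimulus optional [stimulus_field()].
#' @param forced_spikes optional data.frame (cell, time_ms): presynaptic
#'   spikes injected onto a cell's outgoing connections without the cell
#'   itself firing (used by calibration and motif tests).
#' @param neuron_params per-type membrane parameter table.
#' @return list of class `sim_result` with `spikes` (data.frame cell,
#'   time_ms), `delivered` event count, optional voltage traces `v` with
#'   `v_time`, and the resolved configuration.
#' @export
run_network <- function(network, calibration, config,
                        noise = noise_spec(), stimulus = NULL,
                        forced_spikes = NULL,
                        neuron_params = default_neuron_params()) {
  stopifnot(inherits(network, "column_network"), inherits(config, "sim_config"))
  cells <- network$cells
  ncell <- nrow(cells)
  cpar <- absolute_cell_params(neuron_params)
  rest <- vapply(seq_len(nrow(cpar)), function(i) resting_potential(cpar[i, ]),
                 numeric(1))
  ti <- match(cells$type, cpar$cell_type)
  cell_mat <- cbind(cpar$C[ti], cpar$G_leak[ti], cpar$E_leak[ti],
                    cpar$G_Na[ti], cpar$E_Na[ti], cpar$G_Kd[ti],
                    cpar$E_K[ti], cpar$G_M[ti], cpar$V_T[ti],
                    cpar$tau_max[ti], rest[ti])
  dt <- config$dt
  n_steps <- as.integer(round(config$t_total * 1000 / dt))
  syn <- resolve_synapses(network, calibration, dt)
  # sort by presynaptic cell, build CSR offsets
  ord <- order(syn$pre, method = "radix")
  syn <- syn[ord, , drop = FALSE]
  adj_offset <- c(0L, cumsum(tabulate(syn$pre, nbins = ncell)))
  noise_mean <- rep(0, ncell); noise_sd <- rep(0, ncell)
  if (!is.null(noise)) {
    noise_mean[] <- noise$g_mean
    noise_sd[] <- noise$g_sd
  }
  stim_mean <- rep(0, ncell); stim_sd <- rep(0, ncell)
  stim_on <- rep(0L, ncell); stim_off <- rep(0L, ncell)
  if (!is.null(stimulus)) {
    drv <- apply_stimulus(stimulus, network)
    stim_mean[drv$cell] <- drv$g_mean
    stim_sd[drv$cell] <- drv$g_sd
    stim_on[drv$cell] <- as.integer(round(drv$on_s * 1000 / dt))
    stim_off[drv$cell] <- as.integer(round(drv$off_s * 1000 / dt))
  }
  if (is.null(forced_spikes) || nrow(forced_spikes) == 0) {
    f_cell <- integer(0); f_step <- integer(0)
  } else {
    f_step <- pmax(1L, as.integer(ceiling(forced_spikes$time_ms / dt)))
    f_ord <- order(f_step)
    f_cell <- as.integer(forced_spikes$cell[f_ord]) - 1L
    f_step <- f_step[f_ord]
  }
  rec <- config$record_v
  stopifnot(all(rec >= 1 & rec <= ncell))
  out <- .run_network_cpp(cell_mat,
                          as.integer(syn$pre - 1L), as.integer(syn$post - 1L),
                          syn$G, syn$kin, syn$bucket, syn$E,
                          syn$delay_steps, syn$stp_mode, syn$U, syn$U1,
                          syn$tau_rec, syn$tau_facil,
                          as.integer(adj_offset),
                          noise_mean, noise_sd, stim_mean, stim_sd,
                          stim_on, stim_off, f_cell, f_step,
                          dt, n_steps, as.double(config$seed),
                          config$tau_noise, config$mg, config$lockout,
                          as.integer(rec - 1L), config$record_stride,
                          config$syn_stride)
  structure(list(
    spikes = data.frame(cell = out$spike_cell, time_ms = out$spike_time),
    delivered = out$delivered,
    v_time = out$v_time, v = out$v, final_V = out$final_V,
    n_steps = n_steps, config = config), class = "sim_result")
}

#' Step-halving accuracy check
#'
#' Runs the same network/drive configuration at dt and dt/2 and compares
#' per-population binned rate traces (RMS relative difference) and total
#' spike counts. Exceeding the tolerance is reported, not fatal: the
#' result carries pass/fail flags.
#'
#' @param network,calibration,config,noise,stimulus,forced_spikes as in
#'   [run_network()].
#' @param bin_ms comparison bin width (ms).
#' @param tol relative tolerance (default 0.05).
#' @return list with rates at both steps, `rms_rel`, `count_rel`, `pass`.
#' @export
halve_step_check <- function(network, calibration, config,
                             noise = NULL, stimulus = NULL,
                             forced_spikes = NULL, bin_ms = 100, tol = 0.05) {
  cfg2 <- config
  cfg2$dt <- config$dt / 2
  r1 <- run_network(network, calibration, config, noise, stimulus, forced_spikes)
  r2 <- run_network(network, calibration, cfg2, noise, stimulus, forced_spikes)
  t_ms <- config$t_total * 1000
  pc <- network$cells$id[network$cells$type == "PC"]
  b1 <- binned_rate(r1$spikes, pc, t_ms, bin_ms)
  b2 <- binned_rate(r2$spikes, pc, t_ms, bin_ms)
  denom <- sqrt(mean(b1$rate^2))
  rms_rel <- if (denom > 0) sqrt(mean((b1$rate - b2$rate)^2)) / denom else 0
  n1 <- nrow(r1$spikes); n2 <- nrow(r2$spikes)
  count_rel <- if (max(n1, n2) > 0) abs(n1 - n2) / max(n1, n2) else 0
  list(rate_dt = b1, rate_dt2 = b2, rms_rel = rms_rel,
       count_rel = count_rel,
       pass = (rms_rel < tol) && (count_rel < tol))
}
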