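#' Measure a unitary PSP through the network engine
#'
#' Simulates one presynaptic and one postsynaptic cell connected by a
#' single synapse. A forced presynaptic spike (fresh short-term-plasticity
#' state, so the first-spike release scale applies) is delivered to the
#' resting postsynaptic cell and the peak somatic deflection from rest is
#' returned, signed.
#'
#' @param pre_type,post_type cell types ("PC", "BC", "MC", "VIP").
#' @param G peak conductance (uS).
#' @param receptor "AMPA", "NMDA" or "GABA_A".
#' @param stp list/row with mode, U, U1, tau_rec, tau_facil; NULL disables
#'   short-term plasticity (release scale 1).
#' @param dt step (ms).
#' @param mg Mg2+ concentration (mM); the NMDA block is evaluated along
#'   the voltage trajectory from rest unless `clamp_block` is TRUE, in
#'   which case it is held at 1.
#' @param clamp_block hold the NMDA Mg block at 1 during the measurement.
#' @param t_total measurement window (ms); default long enough for the
#'   slow NMDA deflection to peak.
#' @param neuron_params membrane parameter table.
#' @return list with `peak` (mV, signed deflection from rest), `rest`,
#'   `spiked` (did the postsynaptic cell fire), `v` and `time`.
#' @export
measure_psp <- function(pre_type, post_type, G, receptor, stp = NULL,
                        dt = 0.05, mg = 1, clamp_block = FALSE,
                        t_total = if (receptor == "NMDA") 300 else 100,
                        neuron_params = default_neuron_params()) {
  cpar <- absolute_cell_params(neuron_params)
  ti <- match(c(pre_type, post_type), cpar$cell_type)
  stopifnot(!anyNA(ti))
  rest <- vapply(ti, function(i) resting_potential(cpar[i, ]), numeric(1))
  cell_mat <- cbind(cpar$C[ti], cpar$G_leak[ti], cpar$E_leak[ti],
                    cpar$G_Na[ti], cpar$E_Na[ti], cpar$G_Kd[ti],
                    cpar$E_K[ti], cpar$G_M[ti], cpar$V_T[ti],
                    cpar$tau_max[ti], rest)
  kin <- receptor_kinetics()
  kr <- kin[kin$receptor == receptor, ]
  stopifnot(nrow(kr) == 1)
  is_nmda <- kr$mg_block && !clamp_block
  if (is.null(stp)) {
    mode <- 1L; U <- 1; U1 <- 0; tau_rec <- 1; tau_facil <- 0
  } else {
    mode <- if (stp$mode == "depressing") 1L else 2L
    U <- ifelse(is.na(stp$U), 0, stp$U)
    U1 <- ifelse(is.na(stp$U1), 0, stp$U1)
    tau_rec <- stp$tau_rec
    tau_facil <- ifelse(is.na(stp$tau_facil), 0, stp$tau_facil)
  }
  n_steps <- as.integer(round(t_total / dt))
  out <- .run_network_cpp(cell_mat,
                          0L, 1L, G, ifelse(kr$mg_block, 1L, 0L),
                          if (is_nmda) 1L else if (kr$E_rev >= -10) 0L else 2L,
                          kr$E_rev, 1L, mode, U, U1, tau_rec, tau_facil,
                          c(0L, 1L, 1L),
                          rep(0, 2), rep(0, 2), rep(0, 2), rep(0, 2),
                          rep(0L, 2), rep(0L, 2),
                          0L, as.integer(ceiling(2 / dt)),
                          dt, n_steps, 1, 2.7, mg, 2,
                          1L, 1L, 1L)
  v <- out$v[, 1]
  defl <- v - rest[2]
  peak <- defl[which.max(abs(defl))]
  list(peak = peak, rest = rest[2],
       spiked = any(out$spike_cell == 2), v = v, time = out$v_time)
}

#' Calibrate a peak conductance against a unitary PSP amplitude
#'
#' Finds the synaptic peak conductance G such that a single presynaptic
#' spike (fresh short-term-plasticity state) deflects the resting
#' postsynaptic membrane by the target amplitude, via bracketed
#' root-finding on the signed peak. The unitary peak is monotone in G in
#' the subthreshold regime; calibration therefore absorbs the first-spike
#' release scale (U for depressing classes, U1 for facilitating ones) into
#' G.
#'
#' @param pre_type,post_type,receptor,stp,dt,mg,clamp_block,neuron_params
#'   as in [measure_psp()].
#' @param target_mV target unitary PSP amplitude (mV, signed; non-zero).
#' @param tol_mV calibration tolerance on the measured peak (mV).
#' @return list with `G` (uS), `measured` peak (mV).
#' @export
calibrate_peak_conductance <- function(pre_type, post_type, target_mV,
                                       receptor, stp = NULL, dt = 0.05,
                                       mg = 1, clamp_block = TRUE,
                                       tol_mV = 1e-3,
                                       neuron_params = default_neuron_params()) {
  if (is.na(target_mV) || target_mV == 0)
    stop("calibration target must be non-zero")
  f <- function(G) {
    m <- measure_psp(pre_type, post_type, G, receptor, stp, dt, mg,
                     clamp_block, neuron_params = neuron_params)
    if (m$spiked)
      stop("calibration error: target ", target_mV,
           " mV unreachable without spiking the postsynaptic cell")
    m$peak - target_mV
  }
  g_hi <- 1e-6
  while (f(g_hi) * sign(target_mV) < 0) {
    g_hi <- g_hi * 2
    if (g_hi > 50) stop("calibration error: cannot bracket target")
  }
  root <- uniroot(f, c(0, g_hi), tol = 1e-9)
  measured <- root$f.root + target_mV
  if (abs(measured - target_mV) > tol_mV)
    stop("calibration did not converge to tolerance")
  list(G = root$root, measured = measured)
}

#' Calibrate all connection classes
#'
#' Runs [calibrate_peak_conductance()] for every (class, receptor) row of
#' the connection table, using each class's short-term plasticity in the
#' fresh state.
#'
#' @param neuron_params membrane parameter table.
#' @param classes connection-class table ([synapse_table()]).
#' @param lr_dynamics dynamics of the long-range class onto the mediating
#'   interneuron (must match the wiring variant to be simulated).
#' @param dt integration step (ms) used for the PSP measurements; use the
#'   step of the intended network runs.
#' @param mg Mg2+ concentration (mM).
#' @param clamp_block calibrate NMDA with the Mg block held at 1 (the
#'   default: the target is then the maximal-conductance amplitude, which
#'   keeps the NMDA/AMPA peak-conductance ratio physiological; FALSE
#'   calibrates the composite deflection with the block evaluated along
#'   the trajectory from rest, which compensates the block into a much
#'   larger conductance).
#' @return data.frame (class, receptor, target_mV, G, measured_mV).
#' @export
calibrate_synapses <- function(neuron_params = default_neuron_params(),
                               classes = synapse_table(),
                               lr_dynamics = "facilitating",
                               dt = 0.05, mg = 1, clamp_block = TRUE) {
  stp <- resolved_stp_table(lr_dynamics)
  out <- classes[, c("class", "receptor", "amplitude_mV", "pre", "post")]
  out$G <- NA_real_
  out$measured_mV <- NA_real_
  for (i in seq_len(nrow(out))) {
    srow <- stp[stp$class == out$class[i], ]
    cal <- calibrate_peak_conductance(out$pre[i], out$post[i],
                                      out$amplitude_mV[i], out$receptor[i],
                                      srow, dt, mg, clamp_block,
                                      neuron_params = neuron_params)
    out$G[i] <- cal$G
    out$measured_mV[i] <- cal$measured
  }
  names(out)[names(out) == "amplitude_mV"] <- "target_mV"
  out
}
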