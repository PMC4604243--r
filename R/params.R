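#' Default Hodgkin-Huxley parameters for the four cell types
#'
#' Returns the per-type membrane parameters of the single-compartment
#' models: reversal potentials, specific conductances, soma geometry,
#' capacitance, the M-current time-constant scale `tau_max` and the
#' kinetics threshold shift `V_T`. Pyramidal (PC), basket (BC) and
#' Martinotti (MC) columns carry the standard published values; VIP cells
#' reuse the Martinotti column (same soma size as BC/MC, adapting).
#'
#' `V_T` and `tau_max` are not part of the tabulated set. `tau_max`
#' defaults to 1000 ms for every type. `V_T`, which sets each type's spike
#' threshold, defaults to a per-type excitability profile calibrated once
#' for the network operating point (see the methods vignette): pyramidal
#' cells -69 mV, Martinotti cells -69.5 mV, basket cells -72 mV
#' (fast-spiking cells fire at lower thresholds) and VIP cells -70 mV
#' (quiet under background noise, recruited by the selective drive). Both
#' arguments accept a single value or one value per type (PC, BC, MC,
#' VIP).
#'
#' `soma_length` is the length L of the equivalent cylinder; the default
#' (NA) is the iso-dimensional convention L = d.
#'
#' @param V_T kinetics threshold shift (mV); length 1 or 4.
#' @param tau_max M-current time-constant scale (ms); length 1 or 4.
#' @param soma_length cylinder length (um); single value recycled, or NA
#'   for L = d per type.
#' @param bc_adapting keep the tabulated basket-cell `g_M` (default TRUE);
#'   FALSE zeroes it for a strictly non-adapting BC.
#' @return data.frame with one row per cell type (PC, BC, MC, VIP).
#' @export
default_neuron_params <- function(V_T = c(-69, -72, -69.5, -70),
                                  tau_max = 1000,
                                  soma_length = NA, bc_adapting = TRUE) {
  p <- data.frame(
    cell_type = c("PC", "BC", "MC", "VIP"),
    E_leak = c(-70, -70, -70, -70),
    E_Na   = c(50, 50, 50, 50),
    E_K    = c(-100, -100, -100, -100),
    g_leak = c(1e-4, 1.5e-4, 1.5e-4, 1.5e-4),
    g_Na   = c(0.05, 0.05, 0.05, 0.05),
    g_Kd   = c(0.005, 0.01, 0.01, 0.01),
    g_M    = c(7e-5, 9.8e-5, 1e-4, 1e-4),
    soma_diameter = c(96, 67, 67, 67),
    c_m    = c(1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  if (!bc_adapting) p$g_M[p$cell_type == "BC"] <- 0
  p$V_T <- rep_len(V_T, 4)
  p$tau_max <- rep_len(tau_max, 4)
  p$soma_length <- if (length(soma_length) == 1 && is.na(soma_length)) {
    p$soma_diameter
  } else {
    rep_len(soma_length, 4)
  }
  validate_neuron_params(p)
  p
}

validate_neuron_params <- function(p) {
  stopifnot(is.data.frame(p),
            all(c("cell_type", "E_leak", "g_leak", "g_Na", "g_Kd", "g_M",
                  "soma_diameter", "c_m", "V_T", "tau_max",
                  "soma_length") %in% names(p)))
  if (any(p$g_leak < 0 | p$g_Na < 0 | p$g_Kd < 0 | p$g_M < 0))
    stop("conductances must be >= 0")
  if (any(p$soma_diameter <= 0) || any(p$soma_length <= 0))
    stop("soma dimensions must be > 0")
  if (any(p$c_m <= 0)) stop("c_m must be > 0")
  if (any(p$tau_max <= 0)) stop("tau_max must be > 0")
  invisible(p)
}

#' Lateral membrane area of the equivalent-cylinder soma
#'
#' area = pi * d * L in cm^2 with d, L in um. With the iso-dimensional
#' convention L = d (the default when L is missing) this is pi * d^2.
#'
#' @param diameter_um soma diameter (um), > 0.
#' @param length_um cylinder length (um); defaults to the diameter.
#' @return membrane area in cm^2.
#' @export
membrane_area <- function(diameter_um, length_um = diameter_um) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0))
    stop("soma diameter must be > 0")
  if (any(!is.finite(length_um)) || any(length_um <= 0))
    stop("soma length must be > 0")
  pi * diameter_um * length_um * 1e-8
}

#' Absolute membrane quantities per cell type
#'
#' Converts specific conductances (S/cm^2) and capacitance (uF/cm^2) to
#' absolute values over the soma membrane area: conductances in uS,
#' capacitance in nF (so uS x mV = nA and nA / nF = mV/ms).
#'
#' @param p a neuron parameter table ([default_neuron_params()]).
#' @return data.frame with one row per cell type.
#' @export
absolute_cell_params <- function(p = default_neuron_params()) {
  a <- membrane_area(p$soma_diameter, p$soma_length)
  data.frame(
    cell_type = p$cell_type,
    C      = p$c_m * a * 1e3,
    G_leak = p$g_leak * a * 1e6,
    E_leak = p$E_leak,
    G_Na   = p$g_Na * a * 1e6,
    E_Na   = p$E_Na,
    G_Kd   = p$g_Kd * a * 1e6,
    E_K    = p$E_K,
    G_M    = p$g_M * a * 1e6,
    V_T    = p$V_T,
    tau_max = p$tau_max,
    area_cm2 = a,
    stringsAsFactors = FALSE
  )
}

#' Connection-class table: receptors, amplitudes, probabilities, kinetics
#'
#' One row per (connection class, receptor) pair. `amplitude_mV` is the
#' unitary PSP target used by [calibrate_peak_conductance()]; `prob` the
#' Bernoulli connection probability within `scope` (long-range classes use
#' the terminal-field rule instead and have `prob = NA`). Kinetic constants
#' `tau_x`/`tau_s` are in ms (0.05/6 for AMPA and GABA-A, 5/150 for NMDA),
#' `E_rev` in mV.
#'
#' @return data.frame of connection classes.
#' @export
synapse_table <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
class      receptor amplitude_mV prob scope       pre post
PC-PC_LO   AMPA     1.2          0.25 minicolumn  PC  PC
PC-PC_LO   NMDA     0.6          0.25 minicolumn  PC  PC
PC-PC_LR   AMPA     0.3          NA   longrange   PC  PC
PC-PC_LR   NMDA     0.15         NA   longrange   PC  PC
PC-BC      AMPA     1.7          0.70 hypercolumn PC  BC
PC-MC_LO   AMPA     0.1          0.30 minicolumn  PC  MC
PC-MC_LR   AMPA     0.1          NA   longrange   PC  MC
BC-PC      GABA_A  -1.4          0.70 hypercolumn BC  PC
MC-PC      GABA_A  -0.6          0.80 minicolumn  MC  PC
VIP-MC     GABA_A  -0.2          0.60 minicolumn  VIP MC
PC-BC_LR   AMPA     0.1          NA   longrange   PC  BC
")
  kin <- receptor_kinetics()
  tab <- merge(tab, kin, by = "receptor", sort = FALSE)
  tab <- tab[order(match(tab$class, unique(tab$class))), ]
  rownames(tab) <- NULL
  tab
}

#' Receptor kinetic constants
#'
#' First-order kinetic scheme for the open fraction s driven by the fast
#' auxiliary variable x: dx/dt = alpha_x * sum_j delta(t - t_j) - x/tau_x,
#' ds/dt = alpha_s * x * (1 - s) - s/tau_s. alpha_x = 1 (dimensionless),
#' alpha_s = 1 /ms for all receptors.
#'
#' @return data.frame with tau_x, tau_s, E_rev and the Mg-block flag.
#' @export
receptor_kinetics <- function() {
  data.frame(
    receptor = c("AMPA", "NMDA", "GABA_A"),
    tau_x = c(0.05, 5, 0.05),
    tau_s = c(6, 150, 6),
    alpha_x = 1,
    alpha_s = 1,
    E_rev = c(0, 0, -75),
    mg_block = c(FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Short-term plasticity parameters per connection class
#'
#' Depressing classes use a fixed utilisation U with vesicle recovery
#' tau_rec; facilitating classes use the dynamic-utilisation model with
#' increment U1 and facilitation decay tau_facil. The PC-BC row carries
#' depressing dynamics (U = 0.5, tau_rec = 600 ms): its published
#' parameter set has no facilitation constants and basket-cell inputs are
#' described as depressing throughout.
#'
#' @return data.frame keyed by connection class.
#' @export
stp_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
class      mode        U    U1   tau_rec tau_facil
PC-PC_LO   depressing  0.4  NA   600     NA
PC-PC_LR   depressing  0.4  NA   600     NA
PC-BC      depressing  0.5  NA   600     NA
PC-MC_LO   facilitating NA  0.05 20      1000
PC-MC_LR   facilitating NA  0.05 20      1000
BC-PC      depressing  0.25 NA   500     NA
MC-PC      depressing  0.25 NA   500     NA
VIP-MC     depressing  0.25 NA   500     NA
PC-BC_LR   depressing  0.5  NA   600     NA
")
}

#' Short-term plasticity table with variant overrides applied
#'
#' The long-range class onto the mediating interneuron (PC-MC_LR, or
#' PC-BC_LR when long-range inhibition is rerouted through basket cells)
#' takes the wiring variant's dynamics: facilitating reuses the PC-MC
#' constants (U1 = 0.05, tau_rec = 20 ms, tau_facil), depressing the PC-BC
#' constants (U = 0.5, tau_rec = 600 ms). `tau_facil_override` replaces
#' tau_facil of the facilitating PC-MC classes (local and long-range).
#'
#' @param lr_dynamics "facilitating", "depressing" or NULL (table as is).
#' @param tau_facil_override replacement tau_facil (ms) or NULL.
#' @return data.frame like [stp_table()].
#' @export
resolved_stp_table <- function(lr_dynamics = NULL, tau_facil_override = NULL) {
  stp <- stp_table()
  if (!is.null(lr_dynamics) && !is.na(lr_dynamics)) {
    dyn_row <- if (lr_dynamics == "facilitating")
      stp[stp$class == "PC-MC_LR", ] else stp[stp$class == "PC-BC", ]
    for (cl in c("PC-MC_LR", "PC-BC_LR"))
      stp[stp$class == cl, c("mode", "U", "U1", "tau_rec", "tau_facil")] <-
        dyn_row[, c("mode", "U", "U1", "tau_rec", "tau_facil")]
  }
  if (!is.null(tau_facil_override) && !is.na(tau_facil_override)) {
    fac <- stp$mode == "facilitating" & stp$class %in% c("PC-MC_LO", "PC-MC_LR")
    stp$tau_facil[fac] <- tau_facil_override
  }
  stp
}

#' Feedforward stimulus conductance levels
#'
#' The five stimulus strengths (mean point-conductance, uS); `g2` is the
#' default input level.
#'
#' @return named numeric vector.
#' @export
stimulus_levels <- function() {
  c(g1 = 0.0028, g2 = 0.0024, g3 = 0.0020, g4 = 0.0022, g5 = 0.0025)
}
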