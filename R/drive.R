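#' Point-conductance background noise specification
#'
#' Ornstein-Uhlenbeck excitatory conductance (reversal 0 mV) applied to
#' every cell to emulate stochastic synaptic background activity. The
#' default mean (0.000121 uS) is the published background level; the
#' fluctuation sd and correlation time are not published. The default sd
#' (22 x mean) was calibrated once so that the noise-only network holds
#' the 0.5-1 Hz pyramidal background band: at this sd the zero-clipped
#' process acts as a shot-noise-like conductance whose rare excursions
#' trigger the threshold crossings that seed recurrent background events
#' (see the methods vignette). The correlation time defaults to 2.7 ms.
#'
#' @param g_mean mean conductance (uS), >= 0.
#' @param g_sd stationary standard deviation (uS).
#' @param tau_noise correlation time (ms).
#' @param E_rev reversal potential (mV).
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(g_mean = 0.000121, g_sd = 22 * g_mean,
                       tau_noise = 2.7, E_rev = 0) {
  stopifnot(g_mean >= 0, g_sd >= 0, tau_noise > 0)
  structure(list(g_mean = g_mean, g_sd = g_sd, tau_noise = tau_noise,
                 E_rev = E_rev), class = "noise_spec")
}

#' One exact Ornstein-Uhlenbeck conductance step
#'
#' g(t+dt) = mean + (g - mean) e^(-dt/tau) + sd sqrt(1 - e^(-2 dt/tau)) z,
#' clipped at zero; z standard normal. With sd = 0 the process is the
#' constant mean. The injected current is g (E_rev - V).
#'
#' @param spec a [noise_spec()].
#' @param g_prev current conductance value(s) (uS).
#' @param dt step (ms), > 0.
#' @param z standard-normal draw(s); defaults to rnorm.
#' @return updated conductance(s), clipped at 0.
#' @export
noise_conductance_step <- function(spec, g_prev, dt, z = rnorm(length(g_prev))) {
  if (dt <= 0) stop("dt must be > 0")
  a <- exp(-dt / spec$tau_noise)
  g <- spec$g_mean + (g_prev - spec$g_mean) * a +
    spec$g_sd * sqrt(1 - a^2) * z
  pmax(g, 0)
}

#' Feedforward stimulus field
#'
#' Describes which minicolumns receive the layer-4-like feedforward drive,
#' at which conductance level, when, and whether VIP cells in the driven
#' minicolumns additionally receive the locomotion-like selective drive.
#' The drive is the same point-conductance mechanism as the background
#' noise, private to each cell.
#'
#' @param driven data.frame with columns `hc`, `mc` of driven minicolumns.
#' @param level one of the named levels of [stimulus_levels()] (default
#'   "g2") or a numeric mean conductance (uS).
#' @param onset stimulus onset (s).
#' @param duration stimulus duration (s); default 1 s.
#' @param vip_drive NULL/FALSE for no VIP drive, TRUE for the default
#'   selective-drive conductance 0.0018 uS, or a numeric value (uS).
#' @param sd_frac fluctuation sd as a fraction of the mean.
#' @return list of class `stimulus_field`.
#' @export
stimulus_field <- function(driven, level = "g2", onset = 0.2, duration = 1,
                           vip_drive = NULL, sd_frac = 0.5) {
  if (is.character(level)) {
    lv <- stimulus_levels()
    if (!level %in% names(lv)) stop("unknown stimulus level: ", level)
    level <- unname(lv[level])
  }
  vip <- if (is.null(vip_drive) || identical(vip_drive, FALSE)) 0
  else if (isTRUE(vip_drive)) 0.0018 else as.numeric(vip_drive)
  stopifnot(is.data.frame(driven), all(c("hc", "mc") %in% names(driven)),
            level >= 0, duration > 0, onset >= 0, vip >= 0)
  structure(list(driven = driven, level = level, onset = onset,
                 duration = duration, vip_drive = vip, sd_frac = sd_frac),
            class = "stimulus_field")
}

#' Resolve a stimulus field to per-cell drive assignments
#'
#' Every PC in a driven minicolumn receives an independent
#' point-conductance drive with the field's mean level during the stimulus
#' window; when the VIP drive is enabled, VIP cells of the driven
#' minicolumns receive the same mechanism at the selective-drive level.
#'
#' @param field a [stimulus_field()].
#' @param network a `column_network`.
#' @return data.frame (cell, g_mean, g_sd, on_s, off_s).
#' @export
apply_stimulus <- function(field, network) {
  stopifnot(inherits(field, "stimulus_field"))
  cells <- network$cells
  key_net <- paste(cells$hc, cells$mc)
  key_drv <- paste(field$driven$hc, field$driven$mc)
  known <- key_drv %in% paste(cells$hc[!is.na(cells$mc)], cells$mc[!is.na(cells$mc)])
  if (!all(known))
    stop("unknown minicolumn(s): ", paste(key_drv[!known], collapse = "; "))
  pc <- cells$type == "PC" & key_net %in% key_drv
  out <- data.frame(cell = cells$id[pc],
                    g_mean = rep(field$level, sum(pc)),
                    g_sd = rep(field$sd_frac * field$level, sum(pc)),
                    on_s = rep(field$onset, sum(pc)),
                    off_s = rep(field$onset + field$duration, sum(pc)))
  if (field$vip_drive > 0) {
    vip <- cells$type == "VIP" & key_net %in% key_drv
    out <- rbind(out, data.frame(cell = cells$id[vip],
                                 g_mean = field$vip_drive,
                                 g_sd = field$sd_frac * field$vip_drive,
                                 on_s = field$onset,
                                 off_s = field$onset + field$duration))
  }
  out
}
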