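#' Magnesium block factor of the NMDA receptor
#'
#' B(V) = 1 / (1 + [Mg2+] exp(-0.062 V) / 3.57), with [Mg2+] in mM and V
#' in mV.
#'
#' @param V membrane potential (mV), vectorised.
#' @param mg Mg2+ concentration (mM).
#' @return block factor in (0, 1].
#' @export
nmda_block <- function(V, mg = 1) {
  1 / (1 + mg * exp(-0.062 * V) / 3.57)
}

#' Synaptic current of a kinetic receptor
#'
#' I = G s (E_rev - V) for AMPA/GABA-A; NMDA is additionally multiplied by
#' the magnesium block factor [nmda_block()]. Positive values depolarise.
#'
#' @param G peak conductance (uS).
#' @param s open fraction in [0, 1].
#' @param V postsynaptic potential (mV).
#' @param E_rev reversal potential (mV).
#' @param mg_block apply the NMDA Mg block.
#' @param mg Mg2+ concentration (mM).
#' @return current (nA).
#' @export
synaptic_current <- function(G, s, V, E_rev = 0, mg_block = FALSE, mg = 1) {
  stopifnot(all(s >= 0), all(s <= 1), all(G >= 0))
  I <- G * s * (E_rev - V)
  if (mg_block) I <- I * nmda_block(V, mg)
  I
}

#' Advance the two-variable receptor gating by one step
#'
#' The gating pair (x, s) obeys dx/dt = alpha_x sum_j delta(t - t_j) -
#' x/tau_x and ds/dt = alpha_s x (1 - s) - s/tau_s. Spike arrivals add
#' `alpha_x * rel` to x at the start of the step (rel is the short-term
#' plasticity release scale); x then decays exactly and s is advanced with
#' the within-step integral of x driving the bilinear term, which keeps
#' the update accurate even when dt is comparable to tau_x.
#'
#' @param state list with x, s.
#' @param dt step (ms), > 0.
#' @param tau_x,tau_s,alpha_x,alpha_s kinetic constants (see
#'   [receptor_kinetics()]).
#' @param arrivals total release-scaled spike weight arriving this step.
#' @return updated list(x, s).
#' @export
gating_step <- function(state, dt, tau_x, tau_s, alpha_x = 1, alpha_s = 1,
                        arrivals = 0) {
  if (dt <= 0) stop("dt must be > 0")
  x <- state$x + alpha_x * arrivals
  dec_x <- exp(-dt / tau_x)
  xint <- tau_x * (1 - dec_x)
  s <- state$s * exp(-dt / tau_s) + alpha_s * x * xint * (1 - state$s)
  list(x = x * dec_x, s = min(max(s, 0), 1))
}

#' Short-term plasticity update at a presynaptic spike
#'
#' Event-based Tsodyks-Markram recursion. Between spikes the vesicle pool
#' recovers as R <- 1 - (1 - R) exp(-delta/tau_rec) and, in facilitating
#' mode, utilisation decays as u <- u exp(-delta/tau_facil). At the spike,
#' facilitating mode first increments u <- u + U1 (1 - u); the release
#' scale is U R (depressing) or u R (facilitating, post-increment), and
#' the pool is then depleted by that fraction of R.
#'
#' @param stp list/row with mode ("depressing"/"facilitating"), U, U1,
#'   tau_rec, tau_facil.
#' @param state list with R (available fraction) and u (dynamic
#'   utilisation; ignored in depressing mode).
#' @param interval time since the previous spike (ms); Inf for the first
#'   spike of a train.
#' @param increment_first in facilitating mode, apply the U1 increment
#'   before computing release (default TRUE, the dynamic-U convention:
#'   first-spike release is U1 * R).
#' @return list(state = list(R, u), release = release scale in [0, 1]).
#' @export
stp_on_spike <- function(stp, state, interval = Inf, increment_first = TRUE) {
  if (is.na(interval) || interval < 0) stop("spike interval must be >= 0")
  R <- state$R; u <- state$u
  if (is.finite(interval)) {
    R <- 1 - (1 - R) * exp(-interval / stp$tau_rec)
    if (stp$mode == "facilitating" && stp$tau_facil > 0)
      u <- u * exp(-interval / stp$tau_facil)
  }
  if (stp$mode == "facilitating") {
    if (increment_first) u <- u + stp$U1 * (1 - u)
    U_eff <- u
    if (!increment_first) u <- u + stp$U1 * (1 - u)
  } else {
    U_eff <- stp$U
  }
  release <- U_eff * R
  R <- R - release
  list(state = list(R = R, u = u), release = release)
}

#' Release scales for a whole spike train
#'
#' Applies [stp_on_spike()] along a sorted spike train starting from the
#' fresh state (R = 1, u = 0).
#'
#' @param stp plasticity parameters (row of [stp_table()] or list).
#' @param spike_times sorted presynaptic spike times (ms).
#' @param increment_first see [stp_on_spike()].
#' @return list with release (one scale per spike), R and u trajectories
#'   after each spike.
#' @export
stp_release_train <- function(stp, spike_times, increment_first = TRUE) {
  n <- length(spike_times)
  release <- Rout <- uout <- numeric(n)
  state <- list(R = 1, u = 0)
  last <- -Inf
  for (i in seq_len(n)) {
    step <- stp_on_spike(stp, state, spike_times[i] - last, increment_first)
    state <- step$state
    release[i] <- step$release
    Rout[i] <- state$R
    uout[i] <- state$u
    last <- spike_times[i]
  }
  list(release = release, R = Rout, u = uout)
}
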