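#' Voltage-dependent rate functions for the Na and delayed-rectifier channels
#'
#' Evaluates the six transition rates (1/ms) of the Traub-style kinetics
#' with threshold shift `V_T`:
#' \deqn{\alpha_m = -0.32 (V - V_T - 13)/(e^{-(V-V_T-13)/4} - 1)}
#' \deqn{\beta_m = 0.28 (V - V_T - 40)/(e^{(V-V_T-40)/5} - 1)}
#' \deqn{\alpha_h = 0.128 e^{-(V-V_T-17)/18}, \quad
#'       \beta_h = 4/(1 + e^{-(V-V_T-40)/5})}
#' \deqn{\alpha_n = -0.032 (V - V_T - 15)/(e^{-(V-V_T-15)/5} - 1), \quad
#'       \beta_n = 0.5 e^{-(V-V_T-10)/40}}
#' The removable singularities of alpha_m, beta_m and alpha_n are evaluated
#' by their analytic limits, so all six functions are total and continuous.
#'
#' @param V membrane potential (mV), vectorised.
#' @param V_T kinetics threshold shift (mV).
#' @return list with elements alpha_m, beta_m, alpha_h, beta_h, alpha_n,
#'   beta_n (1/ms).
#' @export
rate_functions <- function(V, V_T = -55) {
  u <- V - V_T
  list(
    alpha_m = 1.28 * xexprel(-(u - 13) / 4),
    beta_m  = 1.40 * xexprel((u - 40) / 5),
    alpha_h = 0.128 * exp(-(u - 17) / 18),
    beta_h  = 4 / (1 + exp(-(u - 40) / 5)),
    alpha_n = 0.16 * xexprel(-(u - 15) / 5),
    beta_n  = 0.5 * exp(-(u - 10) / 40)
  )
}

# x / (exp(x) - 1), continuous through x = 0 (value 1). The Na/Kd rate
# constants are all of the form  a * u / (exp(u/k) - 1)  up to sign.
xexprel <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-6
  out[small] <- 1 - x[small] / 2
  out[!small] <- x[!small] / expm1(x[!small])
  out
}

#' M-current steady state and time constant
#'
#' p_inf(V) = 1/(1 + exp(-(V + 35)/10));
#' tau_p(V) = tau_max / (3.3 exp((V + 35)/20) + exp(-(V + 35)/20)).
#'
#' @param V membrane potential (mV), vectorised.
#' @param tau_max time-constant scale (ms), > 0.
#' @return list with p_inf and tau_p (ms).
#' @export
m_current_steady <- function(V, tau_max = 1000) {
  if (any(tau_max <= 0)) stop("tau_max must be > 0")
  u <- (V + 35)
  list(
    p_inf = 1 / (1 + exp(-u / 10)),
    tau_p = tau_max / (3.3 * exp(u / 20) + exp(-u / 20))
  )
}

#' Steady-state gating values at a fixed voltage
#'
#' @param V membrane potential (mV).
#' @param V_T kinetics threshold shift (mV).
#' @param tau_max M-current time-constant scale (ms).
#' @return list with m, h, n, p at their V-dependent steady states.
#' @export
steady_gates <- function(V, V_T = -55, tau_max = 1000) {
  r <- rate_functions(V, V_T)
  p <- m_current_steady(V, tau_max)
  list(m = r$alpha_m / (r$alpha_m + r$beta_m),
       h = r$alpha_h / (r$alpha_h + r$beta_h),
       n = r$alpha_n / (r$alpha_n + r$beta_n),
       p = p$p_inf)
}

#' Time derivatives of the membrane state
#'
#' The membrane equation of the single-compartment model,
#' C dV/dt = -G_leak (V - E_leak) - I_Na - I_Kd - I_M + I_syn, with
#' I_Na = G_Na m^3 h (V - E_Na), I_Kd = G_Kd n^4 (V - E_K),
#' I_M = G_M p (V - E_K), plus first-order gate kinetics. Conductances are
#' absolute (uS), currents in nA, capacitance in nF.
#'
#' @param state list/vector with V, m, h, n, p.
#' @param cpar one row of [absolute_cell_params()].
#' @param I_syn total synaptic/injected current (nA), positive inward.
#' @return list of derivatives dV, dm, dh, dn, dp (per ms).
#' @export
membrane_derivative <- function(state, cpar, I_syn = 0) {
  V <- state$V; m <- state$m; h <- state$h; n <- state$n; p <- state$p
  if (any(!is.finite(c(V, m, h, n, p, I_syn))))
    stop("non-finite membrane state or input")
  r <- rate_functions(V, cpar$V_T)
  mc <- m_current_steady(V, cpar$tau_max)
  I_ion <- cpar$G_leak * (V - cpar$E_leak) +
    cpar$G_Na * m^3 * h * (V - cpar$E_Na) +
    cpar$G_Kd * n^4 * (V - cpar$E_K) +
    cpar$G_M * p * (V - cpar$E_K)
  list(
    dV = (-I_ion + I_syn) / cpar$C,
    dm = r$alpha_m * (1 - m) - r$beta_m * m,
    dh = r$alpha_h * (1 - h) - r$beta_h * h,
    dn = r$alpha_n * (1 - n) - r$beta_n * n,
    dp = (mc$p_inf - p) / mc$tau_p
  )
}

#' Resting membrane potential (noise-free fixed point)
#'
#' Root of the steady-state current balance with all gates at their
#' voltage-dependent equilibria, found by bracketed root-finding between
#' -90 and -40 mV.
#'
#' @param cpar one row of [absolute_cell_params()].
#' @return resting potential (mV).
#' @export
resting_potential <- function(cpar) {
  f <- function(V) {
    g <- steady_gates(V, cpar$V_T, cpar$tau_max)
    -(cpar$G_leak * (V - cpar$E_leak) +
        cpar$G_Na * g$m^3 * g$h * (V - cpar$E_Na) +
        cpar$G_Kd * g$n^4 * (V - cpar$E_K) +
        cpar$G_M * g$p * (V - cpar$E_K))
  }
  # bracket the low (resting) root: the balance curve also crosses zero at
  # the unstable threshold point, so scan upward for the first sign change
  grid <- seq(-95, -40, by = 1)
  fv <- vapply(grid, f, numeric(1))
  i <- which(fv[-length(fv)] > 0 & fv[-1] <= 0)[1]
  if (is.na(i)) stop("no resting fixed point found in [-95, -40] mV")
  uniroot(f, grid[c(i, i + 1)], tol = 1e-10)$root
}

#' Reference single-cell integrator (pure R)
#'
#' Fixed-step integration of one Hodgkin-Huxley cell with optional
#' injected current and optional kinetic synapses driven by prescribed
#' presynaptic spike times. Gates use exponential Euler against their
#' steady states; the voltage uses exponential Euler against the
#' instantaneous conductance-weighted equilibrium. This mirrors the
#' compiled network engine step for step and serves as its independent
#' single-cell reference.
#'
#' @param cpar one row of [absolute_cell_params()].
#' @param t_total total time (ms).
#' @param dt step (ms).
#' @param I_inj constant injected current (nA) or a function of time (ms).
#' @param synapses optional data.frame with one row per synapse:
#'   G (uS), tau_x, tau_s, alpha_x, alpha_s, E_rev, mg_block (logical) and
#'   a list-column `spikes` of presynaptic arrival times (ms); spike
#'   increments are expected to be pre-scaled by the short-term-plasticity
#'   release (see [stp_release_train()]), via an optional list-column
#'   `rel` of per-spike scales.
#' @param mg Mg2+ concentration (mM) for the NMDA block.
#' @param V0 initial voltage; defaults to the resting fixed point.
#' @param record_gates also return gate trajectories.
#' @return list with time (ms), V (mV), spikes (threshold-crossing times),
#'   and optionally m, h, n, p.
#' @export
hh_single_run <- function(cpar, t_total, dt = 0.025, I_inj = 0,
                          synapses = NULL, mg = 1, V0 = NULL,
                          record_gates = FALSE) {
  n_steps <- as.integer(round(t_total / dt))
  if (is.null(V0)) V0 <- resting_potential(cpar)
  g0 <- steady_gates(V0, cpar$V_T, cpar$tau_max)
  V <- V0; m <- g0$m; h <- g0$h; n <- g0$n; p <- g0$p
  Vtr <- numeric(n_steps + 1); Vtr[1] <- V
  if (record_gates) {
    mtr <- htr <- ntr <- ptr <- numeric(n_steps + 1)
    mtr[1] <- m; htr[1] <- h; ntr[1] <- n; ptr[1] <- p
  }
  i_fun <- if (is.function(I_inj)) I_inj else function(t) I_inj
  nsyn <- if (is.null(synapses)) 0L else nrow(synapses)
  if (nsyn > 0) {
    sx <- numeric(nsyn); ss <- numeric(nsyn)
    dec_x <- exp(-dt / synapses$tau_x)
    dec_s <- exp(-dt / synapses$tau_s)
    xint <- synapses$tau_x * (1 - dec_x)   # integral of x over one step
    # per-synapse spike schedule, rounded up to the step grid
    sched <- lapply(seq_len(nsyn), function(i) {
      sp <- synapses$spikes[[i]]
      rel <- if (!is.null(synapses$rel)) synapses$rel[[i]] else rep(1, length(sp))
      list(step = pmax(1L, as.integer(ceiling(sp / dt))), rel = rel)
    })
  }
  spikes <- numeric(0)
  last_spike <- -Inf
  lockout <- 2
  for (k in seq_len(n_steps)) {
    t_now <- (k - 1) * dt
    g_e <- 0; g_nmda <- 0; g_i <- 0; gE_i <- 0; I_const <- i_fun(t_now)
    if (nsyn > 0) {
      for (i in seq_len(nsyn)) {
        hit <- sched[[i]]$step == k
        if (any(hit))
          sx[i] <- sx[i] + synapses$alpha_x[i] * sum(sched[[i]]$rel[hit])
        ss[i] <- ss[i] * dec_s[i] +
          synapses$alpha_s[i] * sx[i] * xint[i] * (1 - ss[i])
        sx[i] <- sx[i] * dec_x[i]
        gc <- synapses$G[i] * ss[i]
        if (isTRUE(synapses$mg_block[i])) {
          g_nmda <- g_nmda + gc
        } else if (synapses$E_rev[i] >= -10) {
          g_e <- g_e + gc
        } else {
          g_i <- g_i + gc
          gE_i <- gE_i + gc * synapses$E_rev[i]
        }
      }
    }
    # gates (exponential Euler at current V)
    r <- rate_functions(V, cpar$V_T)
    mc <- m_current_steady(V, cpar$tau_max)
    m <- exp_euler_gate(m, r$alpha_m, r$beta_m, dt)
    h <- exp_euler_gate(h, r$alpha_h, r$beta_h, dt)
    n <- exp_euler_gate(n, r$alpha_n, r$beta_n, dt)
    p <- p + (mc$p_inf - p) * (1 - exp(-dt / mc$tau_p))
    # voltage (exponential Euler against conductance-weighted equilibrium)
    B <- nmda_block(V, mg)
    g_tot <- cpar$G_leak + cpar$G_Na * m^3 * h + cpar$G_Kd * n^4 +
      cpar$G_M * p + g_e + g_nmda * B + g_i
    A <- cpar$G_leak * cpar$E_leak + cpar$G_Na * m^3 * h * cpar$E_Na +
      (cpar$G_Kd * n^4 + cpar$G_M * p) * cpar$E_K +
      gE_i + I_const                 # g_e, g_nmda have E_rev = 0
    V_inf <- A / g_tot
    V_new <- V_inf + (V - V_inf) * exp(-g_tot * dt / cpar$C)
    t_new <- k * dt
    if (V < 0 && V_new >= 0 && (t_new - last_spike) >= lockout) {
      spikes <- c(spikes, t_new)
      last_spike <- t_new
    }
    V <- V_new
    Vtr[k + 1] <- V
    if (record_gates) {
      mtr[k + 1] <- m; htr[k + 1] <- h; ntr[k + 1] <- n; ptr[k + 1] <- p
    }
  }
  out <- list(time = seq(0, by = dt, length.out = n_steps + 1), V = Vtr,
              spikes = spikes)
  if (record_gates) out <- c(out, list(m = mtr, h = htr, n = ntr, p = ptr))
  out
}

exp_euler_gate <- function(x, alpha, beta, dt) {
  tot <- alpha + beta
  x_inf <- alpha / tot
  x_inf + (x - x_inf) * exp(-tot * dt)
}
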