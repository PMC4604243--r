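# Receptor kinetics, NMDA block, gating integration, short-term plasticity.

test_that("NMDA magnesium block matches the printed formula", {
  expect_equal(nmda_block(0, mg = 1), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  expect_equal(nmda_block(-70, mg = 1), 1 / (1 + exp(0.062 * 70) / 3.57),
               tolerance = 1e-12)
  expect_equal(round(nmda_block(0, 1), 4), 0.7812)
  expect_lt(abs(nmda_block(-70, 1) - 0.0446), 5e-4)
  # block deepens with hyperpolarization and with Mg concentration
  expect_true(all(diff(nmda_block(seq(-90, 0, 5))) > 0))
  expect_lt(nmda_block(-70, 2), nmda_block(-70, 1))
})

test_that("synaptic current is G s (E - V), with the block only for NMDA", {
  expect_equal(synaptic_current(0.01, 0, -70), 0)
  expect_equal(synaptic_current(0.01, 0, -70, E_rev = -75), 0)
  expect_equal(synaptic_current(0.01, 0.5, -60), 0.01 * 0.5 * 60)
  expect_equal(synaptic_current(0.01, 0.5, -60, E_rev = -75),
               0.01 * 0.5 * -15)
  expect_equal(synaptic_current(0.01, 0.5, -60, mg_block = TRUE),
               0.01 * 0.5 * 60 * nmda_block(-60))
  expect_error(synaptic_current(0.01, 1.5, -60))
})

test_that("gating decays exponentially without spikes", {
  st <- list(x = 0, s = 0.4)
  dt <- 0.1
  for (k in 1:50) st <- gating_step(st, dt, tau_x = 0.05, tau_s = 6)
  expect_equal(st$s, 0.4 * exp(-5 / 6), tolerance = 1e-9)
  expect_equal(st$x, 0)
})

test_that("single-spike gating pulse matches a fine-step ODE solution", {
  # independent oracle: forward Euler at dt/100 on
  # dx/dt = -x/tau_x, ds/dt = alpha_s x (1-s) - s/tau_s, x(0+) = 1
  for (kin in list(list(tau_x = 0.05, tau_s = 6),
                   list(tau_x = 5, tau_s = 150))) {
    dt <- 0.01
    fine <- dt / 100
    t_end <- 8 * kin$tau_s
    x <- 1; s <- 0
    n_fine <- as.integer(t_end / fine)
    s_max_fine <- 0
    for (k in seq_len(n_fine)) {
      s <- s + fine * (x * (1 - s) - s / kin$tau_s)
      x <- x - fine * x / kin$tau_x
      if (s > s_max_fine) s_max_fine <- s
    }
    st <- list(x = 1, s = 0)
    s_max <- 0
    s_ok <- TRUE
    for (k in seq_len(as.integer(t_end / dt))) {
      st <- gating_step(st, dt, kin$tau_x, kin$tau_s)
      if (st$s > s_max) s_max <- st$s
      s_ok <- s_ok && st$s >= 0 && st$s <= 1
    }
    expect_true(s_ok)
    expect_lt(abs(s_max - s_max_fine) / s_max_fine, 0.01)
  }
})

test_that("periodic spike input drives s to a periodic steady state", {
  st <- list(x = 0, s = 0)
  dt <- 0.05
  period <- 10 # ms -> 100 Hz
  peaks <- numeric(40)
  for (cycle in 1:40) {
    st <- gating_step(st, dt, 0.05, 6, arrivals = 1)
    pk <- st$s
    for (k in 2:(period / dt)) {
      st <- gating_step(st, dt, 0.05, 6)
      pk <- max(pk, st$s)
    }
    peaks[cycle] <- pk
  }
  expect_lt(abs(peaks[40] - peaks[39]), 1e-6)
  expect_gt(peaks[40], peaks[1])
})

test_that("depressing recursion reproduces the closed-form examples", {
  dep <- list(mode = "depressing", U = 0.4, U1 = NA, tau_rec = 600,
              tau_facil = NA)
  s1 <- stp_on_spike(dep, list(R = 1, u = 0), Inf)
  expect_equal(s1$release, 0.4)
  expect_equal(s1$state$R, 0.6)
  s2 <- stp_on_spike(dep, s1$state, 600)
  R_before <- 1 - 0.4 * exp(-1)
  expect_equal(s2$release, 0.4 * R_before, tolerance = 1e-12)
  expect_error(stp_on_spike(dep, list(R = 1, u = 0), -1), "interval")
})

test_that("facilitating recursion reproduces the closed-form examples", {
  fac <- list(mode = "facilitating", U = NA, U1 = 0.05, tau_rec = 20,
              tau_facil = 1000)
  tr <- stp_release_train(fac, c(0, 20))
  expect_equal(tr$u[1], 0.05)
  u_before2 <- 0.05 * exp(-0.02)
  expect_equal(tr$u[2], u_before2 + 0.05 * (1 - u_before2), tolerance = 1e-12)
  # paired-pulse facilitation at short intervals
  expect_gt(tr$release[2] / tr$release[1], 1)
})

test_that("event recursion matches the fine-step ODE oracle on random trains", {
  set.seed(11)
  specs <- list(
    list(mode = "depressing", U = 0.4, U1 = NA, tau_rec = 600, tau_facil = NA),
    list(mode = "depressing", U = 0.25, U1 = NA, tau_rec = 500, tau_facil = NA),
    list(mode = "facilitating", U = NA, U1 = 0.05, tau_rec = 20,
         tau_facil = 1000))
  for (stp in specs) for (rep in 1:3) {
    n_sp <- 12
    spikes <- sort(round(cumsum(rexp(n_sp, rate = 1 / 40)), 2)) + 1
    spikes <- unique(spikes)
    ev <- stp_release_train(stp, spikes)$release
    ode <- stp_ode_oracle(stp, spikes, dt = 0.005)
    expect_lt(max(abs(ev - ode) / pmax(ode, 1e-12)), 1e-3)
  }
})

test_that("R and dynamic U stay in [0,1] on arbitrary spike trains", {
  set.seed(21)
  for (rep in 1:5) {
    stp <- list(mode = sample(c("depressing", "facilitating"), 1),
                U = runif(1), U1 = runif(1, 0, 0.5),
                tau_rec = runif(1, 10, 1000), tau_facil = runif(1, 10, 2000))
    spikes <- sort(runif(50, 0, 500))
    tr <- stp_release_train(stp, spikes)
    expect_true(all(tr$R >= 0 & tr$R <= 1))
    expect_true(all(tr$u >= 0 & tr$u <= 1))
    expect_true(all(tr$release >= 0 & tr$release <= 1))
  }
})

test_that("regular-train release is monotone per mode and follows the stated trends", {
  train <- seq(0, by = 50, length.out = 20) # 20 Hz
  dep <- list(mode = "depressing", U = 0.4, U1 = NA, tau_rec = 600,
              tau_facil = NA)
  rel_d <- stp_release_train(dep, train)$release
  expect_true(all(diff(rel_d) <= 1e-12))
  fac <- list(mode = "facilitating", U = NA, U1 = 0.05, tau_rec = 20,
              tau_facil = 1000)
  rel_f <- stp_release_train(fac, train)$release
  expect_true(all(diff(rel_f[1:5]) > 0))
  # depression ratio (steady over first release) deepens with U and with
  # tau_rec: large U and tau_rec mean strong depression
  dep_ratio <- function(U, tau_rec) {
    s <- stp_release_train(list(mode = "depressing", U = U, U1 = NA,
                                tau_rec = tau_rec, tau_facil = NA), train)
    mean(tail(s$release, 3)) / s$release[1]
  }
  expect_true(all(diff(vapply(c(0.2, 0.4, 0.6, 0.8), dep_ratio,
                              numeric(1), tau_rec = 600)) < 0))
  expect_true(all(diff(vapply(c(100, 300, 900), function(tr)
    dep_ratio(0.4, tr), numeric(1))) < 0))
  # ... and increasing in tau_facil (facilitating)
  ss_fac <- vapply(c(100, 500, 1500), function(tf) {
    s <- stp_release_train(list(mode = "facilitating", U = NA, U1 = 0.05,
                                tau_rec = 20, tau_facil = tf), train)
    mean(tail(s$release, 3))
  }, numeric(1))
  expect_true(all(diff(ss_fac) > 0))
})
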