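# Compiled integrator: determinism, causality, event accounting, motifs,
# agreement with the pure-R reference integrator, step-halving.

test_that("empty network produces an empty spike record", {
  spec <- network_spec(grid = c(1, 1), seed = 1)
  net <- build_network(spec)
  cal <- calibration_cache()
  res <- run_network(net, cal, sim_config(0.05, seed = 1), noise = NULL)
  expect_equal(nrow(res$spikes), 0)
  expect_equal(res$delivered, 0)
})

test_that("a cell at rest with no input stays within 1 mV for 1 s", {
  net <- motif_network("PC", "PC", "PC-PC_LO", "AMPA")
  cal <- calibration_cache()
  cfg <- sim_config(1, seed = 1, record_v = 2, record_stride = 100)
  res <- run_network(net, cal, cfg, noise = NULL)
  expect_equal(nrow(res$spikes), 0)
  rest <- resting_potential(cp_row("PC"))
  expect_lt(max(abs(res$v[, 1] - rest)), 1)
})

test_that("identical seeds reproduce runs exactly; different seeds differ", {
  net <- build_network(network_spec(grid = c(1, 1), seed = 2))
  cal <- calibration_cache()
  cfg <- sim_config(0.4, seed = 5)
  r1 <- run_network(net, cal, cfg)
  r2 <- run_network(net, cal, cfg)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$final_V, r2$final_V)
  cfg2 <- sim_config(0.4, seed = 6)
  r3 <- run_network(net, cal, cfg2)
  expect_false(identical(r1$final_V, r3$final_V))
})

test_that("delivered events equal spikes weighted by out-degree, and respect delays", {
  net <- build_network(network_spec(grid = c(1, 1), seed = 4))
  cal <- calibration_cache()
  cfg <- sim_config(0.5, seed = 3)
  res <- run_network(net, cal, cfg)
  outdeg <- table(factor(net$edges$pre, levels = net$cells$id))
  expected <- sum(outdeg[as.character(res$spikes$cell)])
  # events scheduled within the horizon arrive; those beyond it don't
  max_delay <- max(net$edges$delay_ms)
  late <- res$spikes$time_ms > 500 - max_delay
  expect_lte(res$delivered, expected)
  expect_gte(res$delivered, expected - sum(outdeg[as.character(res$spikes$cell[late])]))
})

test_that("forced spike through one synapse reproduces the calibrated PSP", {
  cal <- calibration_cache()
  for (cl in list(c("PC-PC_LO", "AMPA", "PC", "PC"),
                  c("BC-PC", "GABA_A", "BC", "PC"))) {
    net <- motif_network(cl[3], cl[4], cl[1], cl[2])
    cfg <- sim_config(0.12, seed = 1, record_v = 2, record_stride = 1,
                      syn_stride = 1)
    res <- run_network(net, cal, cfg, noise = NULL,
                       forced_spikes = data.frame(cell = 1, time_ms = 2))
    rest <- resting_potential(cp_row(cl[4]))
    defl <- res$v[, 1] - rest
    peak <- defl[which.max(abs(defl))]
    target <- cal$target_mV[cal$class == cl[1] & cal$receptor == cl[2]]
    expect_equal(peak, target, tolerance = 0.02)
  }
})

test_that("engine agrees with the pure-R reference integrator on a PSP", {
  cal <- calibration_cache()
  row <- cal[cal$class == "PC-BC" & cal$receptor == "AMPA", ]
  stp <- stp_table()[stp_table()$class == "PC-BC", ]
  net <- motif_network("PC", "BC", "PC-BC", "AMPA")
  dt <- 0.05
  cfg <- sim_config(0.1, dt = dt, seed = 1, record_v = 2, record_stride = 1,
                    syn_stride = 1)
  res <- run_network(net, cal, cfg, noise = NULL,
                     forced_spikes = data.frame(cell = 1, time_ms = 2))
  bc <- cp_row("BC")
  kin <- receptor_kinetics()[receptor_kinetics()$receptor == "AMPA", ]
  syn <- data.frame(G = row$G, tau_x = kin$tau_x, tau_s = kin$tau_s,
                    alpha_x = 1, alpha_s = 1, E_rev = 0, mg_block = FALSE)
  syn$spikes <- list(2 + 1)        # forced spike + 1-step delay
  syn$rel <- list(stp$U)           # first-spike release
  ref <- hh_single_run(bc, t_total = 100, dt = dt, synapses = syn)
  # same scheme, same step: traces agree to a tight tolerance
  expect_lt(max(abs(res$v[, 1] - ref$V[seq_len(nrow(res$v))])), 1e-3)
})

test_that("facilitating PC-MC pathway passes bursts better than slow trains", {
  cal <- calibration_cache()
  net <- motif_network("PC", "MC", "PC-MC_LO", "AMPA")
  peak_depol <- function(rate_hz, n_spikes = 8) {
    times <- 10 + seq(0, by = 1000 / rate_hz, length.out = n_spikes)
    t_tot <- (max(times) + 80) / 1000
    cfg <- sim_config(t_tot, seed = 1, record_v = 2, record_stride = 1,
                      syn_stride = 1)
    res <- run_network(net, cal, cfg, noise = NULL,
                       forced_spikes = data.frame(cell = 1, time_ms = times))
    rest <- resting_potential(cp_row("MC"))
    max(res$v[, 1] - rest)
  }
  # facilitation plus temporal summation: a 70 Hz burst depolarises the
  # Martinotti cell more than the same spikes at 7 Hz
  expect_gt(peak_depol(70), 1.3 * peak_depol(7))
  # the per-spike release is larger for the burst (STP recursion) and
  # grows along it
  fac <- stp_table()[stp_table()$class == "PC-MC_LO", ]
  rel70 <- stp_release_train(fac, seq(0, by = 1000 / 70, length.out = 8))$release
  rel7 <- stp_release_train(fac, seq(0, by = 1000 / 7, length.out = 8))$release
  expect_gt(mean(rel70), mean(rel7))
  expect_gt(rel70[8], 2 * rel70[1])
})

test_that("halving the step changes a deterministic driven run by < 5%", {
  # noise-free, constant suprathreshold drive: purely deterministic
  cal <- calibration_cache()
  net <- build_network(network_spec(grid = c(1, 1), seed = 9))
  stim <- stimulus_field(data.frame(hc = 1, mc = 1), level = 0.006,
                         onset = 0.02, duration = 0.4, sd_frac = 0)
  cfg <- sim_config(0.45, dt = 0.05, seed = 1)
  chk <- halve_step_check(net, cal, cfg, noise = NULL, stimulus = stim,
                          bin_ms = 50)
  expect_gt(sum(chk$rate_dt$rate), 0)
  expect_true(chk$pass)
})

test_that("stimulus drive raises driven-PC rate at every level", {
  cal <- calibration_cache()
  net <- build_network(network_spec(grid = c(1, 1), seed = 11))
  pc <- population_ids(net, "PC", 1, 1)
  base <- run_network(net, cal, sim_config(0.6, seed = 2), noise = noise_spec())
  base_rate <- sum(base$spikes$cell %in% pc & base$spikes$time_ms > 100) /
    length(pc) / 0.5
  for (lv in names(stimulus_levels())) {
    stim <- stimulus_field(data.frame(hc = 1, mc = 1), level = lv,
                           onset = 0.1, duration = 0.5)
    res <- run_network(net, cal, sim_config(0.6, seed = 2),
                       noise = noise_spec(), stimulus = stim)
    rate <- sum(res$spikes$cell %in% pc & res$spikes$time_ms > 100) /
      length(pc) / 0.5
    expect_gt(rate, base_rate + 1)
  }
})
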