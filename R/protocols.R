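#' Reduced desk-scale network specification
#'
#' The experiment presets run at reduced 3 x 3 or 4 x 4 hypercolumn grids
#' (cell counts per column unchanged) so that a full protocol fits on one
#' workstation CPU; all acceptance outcomes at this scale are sign/shape
#' based, not magnitudes.
#'
#' @param variant wiring variant, see [network_spec()].
#' @param grid hypercolumn grid.
#' @param seed construction seed.
#' @param ... further arguments to [network_spec()].
#' @return a `network_spec`.
#' @export
reduced_network_spec <- function(variant = "Type1", grid = c(3, 3), seed = 1,
                                 ...) {
  network_spec(grid = grid, variant = variant, seed = seed, ...)
}

# Shared machinery: run n_trials simulations of one (network, stimulus)
# condition and return the spike tables.
run_trials <- function(network, calibration, stimulus, noise, n_trials,
                       seed, t_total, neuron_params, dt = 0.05) {
  lapply(seq_len(n_trials), function(k) {
    cfg <- sim_config(t_total = t_total, dt = dt, seed = seed + k)
    run_network(network, calibration, cfg, noise = noise,
                stimulus = stimulus, neuron_params = neuron_params)$spikes
  })
}

population_ids <- function(network, type, hc = NULL, mc = NULL) {
  cells <- network$cells
  sel <- cells$type == type
  if (!is.null(hc)) sel <- sel & cells$hc == hc
  if (!is.null(mc)) sel <- sel & !is.na(cells$mc) & cells$mc == mc
  ids <- cells$id[sel]
  if (length(ids) == 0) stop("empty population")
  ids
}

# hypercolumns ordered by distance from the grid centroid
hc_by_centrality <- function(grid) {
  idx <- seq_len(prod(grid))
  row <- (idx - 1) %/% grid[2] + 1
  col <- (idx - 1) %% grid[2] + 1
  d <- (row - mean(row))^2 + (col - mean(col))^2
  idx[order(d, idx)]
}

# k mutually distant hypercolumns (greedy max-min on grid coordinates)
hc_spread <- function(grid, k) {
  idx <- seq_len(prod(grid))
  row <- (idx - 1) %/% grid[2] + 1
  col <- (idx - 1) %% grid[2] + 1
  chosen <- 1L
  while (length(chosen) < k) {
    dmin <- vapply(idx, function(i) {
      min((row[i] - row[chosen])^2 + (col[i] - col[chosen])^2)
    }, numeric(1))
    dmin[chosen] <- -1
    chosen <- c(chosen, which.max(dmin))
  }
  sort(chosen)
}

experiment_defaults <- function(n_trials, seed, neuron_params, noise,
                                calibration, lr_dynamics = "facilitating") {
  np <- if (is.null(neuron_params)) default_neuron_params() else neuron_params
  ns <- if (is.null(noise)) noise_spec() else noise
  cal <- if (is.null(calibration))
    calibrate_synapses(np, lr_dynamics = lr_dynamics) else calibration
  list(np = np, ns = ns, cal = cal, n_trials = n_trials, seed = seed)
}

#' Size-dependent suppression experiment
#'
#' Applies a small stimulus (3 minicolumns of one pattern in mutually
#' distant hypercolumns) and a large stimulus (the whole pattern) to a
#' wiring with long-range Martinotti recruitment and to one without it,
#' and records PC/BC/MC rates of a randomly chosen driven minicolumn.
#' With the Martinotti long-range pathway, PC and BC respond less to the
#' large stimulus (surround suppression) while MC respond more; without
#' it, responses grow with stimulus size.
#'
#' @param grid hypercolumn grid (reduced desk scale).
#' @param n_trials trials per condition (averaged).
#' @param level stimulus level name or conductance (uS).
#' @param onset,duration stimulus window (s).
#' @param seed base seed (construction uses it; trial k runs at seed + k).
#' @param neuron_params,noise,calibration optional overrides; calibration
#'   is computed from the parameters when omitted.
#' @param bin_ms analysis bin (ms).
#' @return list report: rate traces per (wiring, stimulus, population),
#'   stimulus-window means, suppression indicators
#'   (rate_large - rate_small per population), and the resolved config.
#' @export
run_size_tuning_experiment <- function(grid = c(4, 4), n_trials = 3,
                                       level = "g2", onset = 0.3,
                                       duration = 1.2, seed = 1,
                                       neuron_params = NULL, noise = NULL,
                                       calibration = NULL, bin_ms = 100) {
  ed <- experiment_defaults(n_trials, seed, neuron_params, noise, calibration)
  n_hc <- prod(grid)
  small_hcs <- hc_spread(grid, 3)
  pattern <- 1L
  t_total <- onset + duration
  stim_small <- stimulus_field(data.frame(hc = small_hcs, mc = pattern),
                               level = level, onset = onset, duration = duration)
  stim_large <- stimulus_field(data.frame(hc = seq_len(n_hc), mc = pattern),
                               level = level, onset = onset, duration = duration)
  set.seed(seed)
  rec_hc <- small_hcs[sample.int(length(small_hcs), 1)]
  out <- list()
  for (wiring in c("with_lr_mc", "without_lr_mc")) {
    variant <- if (wiring == "with_lr_mc") "Type1" else "Type5"
    net <- build_network(network_spec(grid = grid, variant = variant,
                                      seed = seed, compensate = FALSE))
    pops <- list(PC = population_ids(net, "PC", rec_hc, pattern),
                 BC = population_ids(net, "BC", rec_hc),
                 MC = population_ids(net, "MC", rec_hc, pattern))
    for (sz in c("small", "large")) {
      stim <- if (sz == "small") stim_small else stim_large
      trials <- run_trials(net, ed$cal, stim, ed$ns, n_trials, seed,
                           t_total, ed$np)
      for (pop in names(pops)) {
        tr <- binned_rate(trials, pops[[pop]], t_total * 1000, bin_ms)
        out[[wiring]][[sz]][[pop]] <- list(
          trace = tr,
          stim_mean = window_mean(tr, onset * 1000, (onset + duration) * 1000))
      }
    }
  }
  indicators <- lapply(out, function(w) {
    sapply(names(w$small), function(pop)
      w$large[[pop]]$stim_mean - w$small[[pop]]$stim_mean)
  })
  list(rates = out, suppression_indicator = indicators,
       config = list(grid = grid, n_trials = n_trials, level = level,
                     onset = onset, duration = duration, seed = seed,
                     recorded_hc = rec_hc, pattern = pattern,
                     small_hcs = small_hcs, bin_ms = bin_ms))
}

#' Contextual-contrast (center saliency) experiment
#'
#' Full-field stimulation under two layouts: homogeneous (every
#' hypercolumn drives the recorded pattern) and center-contrast (only the
#' recorded hypercolumn drives the recorded pattern; all others drive a
#' different one). With the long-range Martinotti pathway the contrasting
#' center responds more than the homogeneous one; without it the ordering
#' reverses.
#'
#' @inheritParams run_size_tuning_experiment
#' @return list report with PC rate traces, stimulus-window means, and the
#'   saliency indicator (contrast - homogeneous) per wiring.
#' @export
run_contrast_experiment <- function(grid = c(3, 3), n_trials = 3,
                                    level = "g2", onset = 0.3,
                                    duration = 1.2, seed = 1,
                                    neuron_params = NULL, noise = NULL,
                                    calibration = NULL, bin_ms = 100) {
  ed <- experiment_defaults(n_trials, seed, neuron_params, noise, calibration)
  n_hc <- prod(grid)
  rec_hc <- hc_by_centrality(grid)[1]
  pat_a <- 1L; pat_b <- 2L
  t_total <- onset + duration
  layouts <- list(
    homogeneous = data.frame(hc = seq_len(n_hc), mc = pat_a),
    contrast = data.frame(hc = seq_len(n_hc),
                          mc = ifelse(seq_len(n_hc) == rec_hc, pat_a, pat_b)))
  out <- list()
  for (wiring in c("with_lr_mc", "without_lr_mc")) {
    variant <- if (wiring == "with_lr_mc") "Type1" else "Type5"
    net <- build_network(network_spec(grid = grid, variant = variant,
                                      seed = seed, compensate = FALSE))
    pc <- population_ids(net, "PC", rec_hc, pat_a)
    for (ly in names(layouts)) {
      stim <- stimulus_field(layouts[[ly]], level = level, onset = onset,
                             duration = duration)
      trials <- run_trials(net, ed$cal, stim, ed$ns, n_trials, seed,
                           t_total, ed$np)
      tr <- binned_rate(trials, pc, t_total * 1000, bin_ms)
      out[[wiring]][[ly]] <- list(
        trace = tr,
        stim_mean = window_mean(tr, onset * 1000, (onset + duration) * 1000))
    }
  }
  indicators <- vapply(out, function(w)
    w$contrast$stim_mean - w$homogeneous$stim_mean, numeric(1))
  list(rates = out, saliency_indicator = indicators,
       config = list(grid = grid, n_trials = n_trials, level = level,
                     onset = onset, duration = duration, seed = seed,
                     recorded_hc = rec_hc, bin_ms = bin_ms))
}

#' Center-surround response of the wiring variants
#'
#' Drives a center block (pattern A) and the surrounding hypercolumns
#' (pattern B) simultaneously and computes the saliency statistic delta =
#' PC rate at the center site minus PC rate at the surround site for each
#' requested wiring variant, plus optional facilitation-time-constant
#' sweeps of the reference wiring.
#'
#' @inheritParams run_size_tuning_experiment
#' @param variants character vector of variants ("Type1".."Type6").
#' @param levels stimulus level names used for the variant runs.
#' @param tau_facil_values optional tau_facil (ms) sweep for the reference
#'   Martinotti wiring (run at `tau_levels`).
#' @param tau_levels stimulus levels for the tau_facil sweep.
#' @param tau_duration stimulus duration (s) for the tau_facil sweep
#'   (longer, so the positive-delta duration can be compared).
#' @return list report with delta traces and summaries per run: mean delta
#'   over the stimulus window, peak delta, and the positive duration
#'   (consecutive bins with delta > 0 from stimulus onset).
#' @export
run_variant_experiment <- function(variants = paste0("Type", 1:6),
                                   grid = c(4, 4), n_trials = 3,
                                   levels = "g2", onset = 0.3,
                                   duration = 1.2, seed = 1,
                                   tau_facil_values = NULL,
                                   tau_levels = "g4", tau_duration = 1.4,
                                   neuron_params = NULL, noise = NULL,
                                   calibration = NULL, bin_ms = 100) {
  np <- if (is.null(neuron_params)) default_neuron_params() else neuron_params
  ns <- if (is.null(noise)) noise_spec() else noise
  n_hc <- prod(grid)
  pat_a <- 1L; pat_b <- 2L
  center_hcs <- center_block(grid)
  surround_hcs <- setdiff(seq_len(n_hc), center_hcs)
  site1_hc <- center_hcs[1]
  site2_hc <- farthest_hc(grid, center_hcs)
  driven <- data.frame(hc = seq_len(n_hc),
                       mc = ifelse(seq_len(n_hc) %in% center_hcs, pat_a, pat_b))
  one_run <- function(variant, level, tau_override, dur) {
    spec <- network_spec(grid = grid, variant = variant, seed = seed,
                         tau_facil_override = tau_override)
    net <- build_network(spec)
    dyn <- spec$lr_dynamics %||% "facilitating"
    cal <- if (is.null(calibration)) calibrate_synapses(np, lr_dynamics = dyn)
    else patch_lr_calibration(calibration, np, dyn)
    stim <- stimulus_field(driven, level = level, onset = onset, duration = dur)
    t_total <- onset + dur
    trials <- run_trials(net, cal, stim, ns, n_trials, seed, t_total, np)
    r1 <- binned_rate(trials, population_ids(net, "PC", site1_hc, pat_a),
                      t_total * 1000, bin_ms)
    r2 <- binned_rate(trials, population_ids(net, "PC", site2_hc, pat_b),
                      t_total * 1000, bin_ms)
    dl <- delta_trace(r1, r2)
    within <- dl$bin_edges[-1] > onset * 1000 &
      dl$bin_edges[-length(dl$bin_edges)] >= onset * 1000 &
      dl$bin_edges[-1] <= (onset + dur) * 1000
    dvals <- dl$delta[within]
    pos_run <- 0
    for (v in dvals) { if (v > 0) pos_run <- pos_run + 1 else break }
    list(delta = dl, rate_site1 = r1, rate_site2 = r2,
         mean_delta = mean(dvals), peak_delta = max(dvals),
         positive_duration_ms = pos_run * bin_ms,
         sign_reversed = pos_run >= 1 && any(dvals[-seq_len(pos_run)] < 0))
  }
  runs <- list()
  for (variant in variants) for (lv in levels)
    runs[[paste(variant, lv, sep = ".")]] <- one_run(variant, lv, NULL, duration)
  tau_runs <- list()
  for (tf in tau_facil_values) for (lv in tau_levels)
    tau_runs[[paste0("tau", tf, ".", lv)]] <-
      one_run("Type1", lv, tf, tau_duration)
  list(runs = runs, tau_runs = tau_runs,
       summary = data.frame(
         run = names(runs),
         mean_delta = vapply(runs, function(r) r$mean_delta, numeric(1)),
         positive_duration_ms = vapply(runs, function(r)
           r$positive_duration_ms, numeric(1))),
       config = list(grid = grid, n_trials = n_trials, levels = levels,
                     onset = onset, duration = duration, seed = seed,
                     center_hcs = center_hcs, site1_hc = site1_hc,
                     site2_hc = site2_hc,
                     tau_facil_values = tau_facil_values,
                     tau_levels = tau_levels, bin_ms = bin_ms))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# Re-calibrate the long-range interneuron class when a supplied
# calibration was computed under the other short-term dynamics (the
# first-spike release differs between modes, so G does too).
patch_lr_calibration <- function(cal, np, lr_dynamics) {
  stp <- resolved_stp_table(lr_dynamics)
  for (cl in c("PC-BC_LR", "PC-MC_LR")) {
    i <- which(cal$class == cl)
    if (!length(i)) next
    srow <- stp[stp$class == cl, ]
    new <- calibrate_peak_conductance(cal$pre[i], cal$post[i],
                                      cal$target_mV[i], cal$receptor[i],
                                      srow, neuron_params = np)
    cal$G[i] <- new$G
    cal$measured_mV[i] <- new$measured
  }
  cal
}

# top-left 2x2 block of hypercolumns (or a single one on degenerate grids)
center_block <- function(grid) {
  rows <- min(2, grid[1]); cols <- min(2, grid[2])
  as.integer(outer(seq_len(rows) - 1, seq_len(cols), function(r, c)
    r * grid[2] + c))
}

farthest_hc <- function(grid, from) {
  idx <- seq_len(prod(grid))
  row <- (idx - 1) %/% grid[2] + 1
  col <- (idx - 1) %% grid[2] + 1
  d <- vapply(idx, function(i)
    min((row[i] - row[from])^2 + (col[i] - col[from])^2), numeric(1))
  which.max(d)
}

#' VIP-mediated disinhibition experiment
#'
#' Size series on the reference wiring: the stimulus drives the pattern in
#' a growing set of hypercolumns, with and without the selective VIP drive
#' in the driven minicolumns. Reports size-tuning curves (mean PC rate of
#' the recorded minicolumn over the stimulus window), their difference,
#' and the control curve's suppression shape.
#'
#' @inheritParams run_size_tuning_experiment
#' @param sizes numbers of driven minicolumns (>= 4 values).
#' @param vip_drive selective-drive conductance (uS) for the VIP-on
#'   condition.
#' @return list report with the [size_tuning()] table (raw and
#'   normalized), per-size rates, and the resolved config.
#' @export
run_disinhibition_experiment <- function(sizes = c(1, 3, 6, 9),
                                         grid = c(3, 3), n_trials = 3,
                                         level = "g2", onset = 0.3,
                                         duration = 1.2, seed = 1,
                                         vip_drive = 0.0018,
                                         neuron_params = NULL, noise = NULL,
                                         calibration = NULL, bin_ms = 100) {
  if (length(sizes) < 4) stop("need at least 4 stimulus sizes")
  if (max(sizes) > prod(grid)) stop("size exceeds the number of hypercolumns")
  ed <- experiment_defaults(n_trials, seed, neuron_params, noise, calibration)
  pattern <- 1L
  order_hc <- hc_by_centrality(grid)
  rec_hc <- order_hc[1]
  net <- build_network(network_spec(grid = grid, variant = "Type1",
                                    seed = seed))
  pc <- population_ids(net, "PC", rec_hc, pattern)
  t_total <- onset + duration
  resp <- function(size, vip) {
    driven <- data.frame(hc = order_hc[seq_len(size)], mc = pattern)
    stim <- stimulus_field(driven, level = level, onset = onset,
                           duration = duration,
                           vip_drive = if (vip) vip_drive else NULL)
    trials <- run_trials(net, ed$cal, stim, ed$ns, n_trials, seed,
                         t_total, ed$np)
    tr <- binned_rate(trials, pc, t_total * 1000, bin_ms)
    window_mean(tr, onset * 1000, (onset + duration) * 1000)
  }
  control <- vapply(sizes, resp, numeric(1), vip = FALSE)
  disinhibited <- vapply(sizes, resp, numeric(1), vip = TRUE)
  tuning <- size_tuning(sizes, control, disinhibited, normalize = TRUE)
  list(tuning = tuning,
       raw = data.frame(size = sizes, control = control,
                        disinhibited = disinhibited,
                        difference = disinhibited - control),
       config = list(grid = grid, sizes = sizes, n_trials = n_trials,
                     level = level, onset = onset, duration = duration,
                     seed = seed, recorded_hc = rec_hc,
                     vip_drive = vip_drive, bin_ms = bin_ms))
}
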