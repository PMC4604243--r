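#' Network specification
#'
#' Geometry, cell counts, wiring variant and construction seed for a
#' hypercolumn/minicolumn patch. The full-scale default is a 6 x 6 grid of
#' hypercolumns (500 um diameter, 3 x 3 mm patch), six minicolumns per
#' hypercolumn, 30 PC + 3 MC + 3 VIP per minicolumn and 8 BC per
#' hypercolumn, with a mean conduction speed of 0.3 m/s.
#'
#' Variant presets configure three flags:
#' \itemize{
#' \item Type1: long-range terminals onto MC, facilitating, MC inhibition
#'   minicolumn-specific (the reference wiring).
#' \item Type2: long-range onto BC (hypercolumn-wide, i.e. orientation
#'   unspecific), facilitating dynamics.
#' \item Type3: long-range onto BC, depressing dynamics.
#' \item Type4: long-range onto MC with the MC pool merged across the
#'   hypercolumn (orientation unspecific).
#' \item Type5: no long-range inhibition (the interneuron terminal is
#'   dropped; only PC-PC long-range remains).
#' \item Type6: long-range onto orientation-specific BC (each BC is
#'   assigned one minicolumn and wires only with it).
#' }
#' Variants that change interneuron pooling or rerouting are weight
#' compensated against the Type1 reference (see [compensate_weights()])
#' unless `compensate = FALSE`.
#'
#' @param grid c(rows, cols) of hypercolumns.
#' @param minicolumns_per_hc minicolumns per hypercolumn.
#' @param pc_per_mc,mc_per_mc,vip_per_mc cells per minicolumn.
#' @param bc_per_hc basket cells per hypercolumn.
#' @param hc_diameter hypercolumn diameter (um), also the lattice spacing.
#' @param conduction_speed_mean,conduction_speed_sd Gaussian conduction
#'   speed (m/s); draws are truncated at 5% of the mean.
#' @param variant "Type1".."Type6".
#' @param tau_facil_override replacement facilitation time constant (ms)
#'   for the PC-MC classes, or NULL.
#' @param compensate apply weight compensation against the Type1 reference.
#' @param seed construction seed.
#' @return list of class `network_spec`.
#' @export
network_spec <- function(grid = c(6, 6), minicolumns_per_hc = 6,
                         pc_per_mc = 30, mc_per_mc = 3, vip_per_mc = 3,
                         bc_per_hc = 8, hc_diameter = 500,
                         conduction_speed_mean = 0.3,
                         conduction_speed_sd = 0.2 * 0.3,
                         variant = "Type1", tau_facil_override = NULL,
                         compensate = TRUE, seed = 1) {
  variant <- match.arg(variant, paste0("Type", 1:6))
  flags <- switch(variant,
    Type1 = list(lr_target = "MC", lr_dynamics = "facilitating",
                 orientation = "specific"),
    Type2 = list(lr_target = "BC", lr_dynamics = "facilitating",
                 orientation = "unspecific"),
    Type3 = list(lr_target = "BC", lr_dynamics = "depressing",
                 orientation = "unspecific"),
    Type4 = list(lr_target = "MC", lr_dynamics = "facilitating",
                 orientation = "unspecific"),
    Type5 = list(lr_target = "none", lr_dynamics = NA,
                 orientation = "specific"),
    Type6 = list(lr_target = "BC", lr_dynamics = "depressing",
                 orientation = "specific"))
  spec <- list(grid = grid, minicolumns_per_hc = minicolumns_per_hc,
               pc_per_mc = pc_per_mc, mc_per_mc = mc_per_mc,
               vip_per_mc = vip_per_mc, bc_per_hc = bc_per_hc,
               hc_diameter = hc_diameter,
               conduction_speed_mean = conduction_speed_mean,
               conduction_speed_sd = conduction_speed_sd,
               variant = variant,
               lr_target = flags$lr_target, lr_dynamics = flags$lr_dynamics,
               interneuron_orientation = flags$orientation,
               tau_facil_override = tau_facil_override,
               compensate = compensate, seed = seed)
  stopifnot(all(grid >= 1), minicolumns_per_hc >= 1, pc_per_mc >= 5,
            mc_per_mc >= 1, bc_per_hc >= 1)
  class(spec) <- "network_spec"
  spec
}

# Bernoulli edges between two id vectors (no self-connections).
bernoulli_edges <- function(pre_ids, post_ids, prob) {
  pre <- rep(pre_ids, times = length(post_ids))
  post <- rep(post_ids, each = length(pre_ids))
  keep <- (pre != post) & (runif(length(pre)) < prob)
  data.frame(pre = pre[keep], post = post[keep])
}

#' Build a hypercolumn/minicolumn network
#'
#' Places cells (uniform within each hypercolumn's 500 um disc, z
#' jittered +/- 50 um), realises every local connection class as
#' independent Bernoulli draws at its tabulated probability within its
#' scope, wires long-range projections by the terminal-field rule (each PC
#' innervates 4 PC and 1 interneuron in one same-pattern minicolumn of
#' another hypercolumn), applies the variant's re-scoping and weight
#' compensation, and assigns conduction delays.
#'
#' @param spec a [network_spec()].
#' @return list of class `column_network` with `cells`, `edges` and the
#'   spec.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  net <- build_network_raw(spec)
  net <- compensate_weights(net)
  set.seed(spec$seed + 1L)
  net <- assign_delays(net)
  net
}

build_network_raw <- function(spec) {
  n_hc <- prod(spec$grid)
  n_mc <- spec$minicolumns_per_hc
  # --- cells ---------------------------------------------------------------
  hc_idx <- seq_len(n_hc)
  hc_row <- (hc_idx - 1) %/% spec$grid[2] + 1
  hc_col <- (hc_idx - 1) %% spec$grid[2] + 1
  hc_x <- (hc_col - 1) * spec$hc_diameter
  hc_y <- (hc_row - 1) * spec$hc_diameter
  per_hc <- n_mc * (spec$pc_per_mc + spec$mc_per_mc + spec$vip_per_mc) +
    spec$bc_per_hc
  type <- hc <- mc <- integer(0)
  rows <- vector("list", n_hc)
  for (hcc in hc_idx) {
    t_mc <- rep(c("PC", "MC", "VIP"),
                times = c(spec$pc_per_mc, spec$mc_per_mc, spec$vip_per_mc))
    rows[[hcc]] <- data.frame(
      type = c(rep(t_mc, n_mc), rep("BC", spec$bc_per_hc)),
      hc = hcc,
      mc = c(rep(seq_len(n_mc), each = length(t_mc)),
             rep(NA_integer_, spec$bc_per_hc)),
      stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, rows)
  cells$id <- seq_len(nrow(cells))
  ncell <- nrow(cells)
  r <- spec$hc_diameter / 2 * sqrt(runif(ncell))
  th <- runif(ncell, 0, 2 * pi)
  cells$x <- hc_x[cells$hc] + r * cos(th)
  cells$y <- hc_y[cells$hc] + r * sin(th)
  cells$z <- runif(ncell, -50, 50)
  # orientation of each BC: only used by the orientation-specific BC
  # variant (Type6); assigned cyclically over minicolumn indices
  cells$bc_orient <- NA_integer_
  is_bc <- cells$type == "BC"
  cells$bc_orient[is_bc] <- (seq_len(sum(is_bc)) - 1L) %% n_mc + 1L
  cells <- cells[, c("id", "type", "hc", "mc", "bc_orient", "x", "y", "z")]

  # --- local connection classes -------------------------------------------
  tab <- synapse_table()
  local_tab <- unique(tab[tab$scope != "longrange",
                          c("class", "prob", "scope", "pre", "post")])
  mc_scope_wide <- spec$lr_target == "MC" &&
    spec$interneuron_orientation == "unspecific"   # Type4 pooled MC
  bc_specific <- spec$lr_target == "BC" &&
    spec$interneuron_orientation == "specific"     # Type6 tuned BC
  edge_list <- list()
  for (ci in seq_len(nrow(local_tab))) {
    cl <- local_tab[ci, ]
    scope <- cl$scope
    involves_mc_cells <- cl$pre == "MC" || cl$post == "MC"
    if (mc_scope_wide && involves_mc_cells && scope == "minicolumn")
      scope <- "hypercolumn"
    parts <- list()
    if (scope == "minicolumn") {
      for (hcc in hc_idx) for (mcc in seq_len(n_mc)) {
        pre_ids <- cells$id[cells$type == cl$pre & cells$hc == hcc &
                              !is.na(cells$mc) & cells$mc == mcc]
        post_ids <- cells$id[cells$type == cl$post & cells$hc == hcc &
                               !is.na(cells$mc) & cells$mc == mcc]
        parts[[length(parts) + 1L]] <- bernoulli_edges(pre_ids, post_ids, cl$prob)
      }
    } else { # hypercolumn scope (PC-BC, BC-PC, or widened MC classes)
      for (hcc in hc_idx) {
        pre_ids <- cells$id[cells$type == cl$pre & cells$hc == hcc]
        post_ids <- cells$id[cells$type == cl$post & cells$hc == hcc]
        if (bc_specific && (cl$pre == "BC" || cl$post == "BC")) {
          # orientation-specific BC wire only with their own minicolumn
          for (mcc in seq_len(n_mc)) {
            pre_k <- pre_ids[bc_match(cells, pre_ids, mcc)]
            post_k <- post_ids[bc_match(cells, post_ids, mcc)]
            parts[[length(parts) + 1L]] <- bernoulli_edges(pre_k, post_k, cl$prob)
          }
        } else {
          parts[[length(parts) + 1L]] <- bernoulli_edges(pre_ids, post_ids, cl$prob)
        }
      }
    }
    e <- do.call(rbind, parts)
    if (nrow(e)) {
      e$class <- cl$class
      edge_list[[length(edge_list) + 1L]] <- e
    }
  }
  edges <- do.call(rbind, edge_list)
  # expand receptors: PC-PC classes carry both AMPA and NMDA on the same
  # anatomical contact (one Bernoulli draw, two receptor instances)
  edges <- merge(edges, unique(tab[, c("class", "receptor")]), by = "class")

  # --- long-range terminal fields -----------------------------------------
  lr <- long_range_wiring(cells, spec)
  edges <- rbind(edges[, c("pre", "post", "class", "receptor")],
                 lr[, c("pre", "post", "class", "receptor")])
  if (anyDuplicated(edges[, c("pre", "post", "class", "receptor")]) > 0)
    edges <- unique(edges)
  edges$weight_scale <- 1
  rownames(edges) <- NULL
  structure(list(spec = spec, cells = cells, edges = edges,
                 n_hc = n_hc), class = "column_network")
}

bc_match <- function(cells, ids, mcc) {
  sub <- cells[match(ids, cells$id), ]
  ifelse(sub$type == "BC", !is.na(sub$bc_orient) & sub$bc_orient == mcc,
         !is.na(sub$mc) & sub$mc == mcc)
}

#' Long-range terminal-field wiring
#'
#' Every PC selects one target minicolumn uniformly among same-pattern
#' minicolumns of other hypercolumns (the pattern of a minicolumn is its
#' index within the hypercolumn) and innervates 4 distinct PC plus one
#' interneuron there: an MC of the target minicolumn (`lr_target = "MC"`;
#' any MC of the target hypercolumn when the MC pool is unspecific), a BC
#' of the target hypercolumn (`lr_target = "BC"`; the orientation-matched
#' BC when BC are orientation specific), or none (`lr_target = "none"`).
#' PC-PC long-range contacts carry AMPA and NMDA.
#'
#' @param cells cell table of a network under construction.
#' @param spec the [network_spec()].
#' @return data.frame of long-range edges.
#' @keywords internal
#' @export
long_range_wiring <- function(cells, spec) {
  n_hc <- prod(spec$grid)
  empty <- data.frame(pre = integer(0), post = integer(0),
                      class = character(0), receptor = character(0))
  if (n_hc < 2) return(empty)
  pcs <- cells[cells$type == "PC", ]
  pre <- post <- integer(0)
  in_pre <- in_post <- integer(0)
  for (i in seq_len(nrow(pcs))) {
    pat <- pcs$mc[i]
    own_hc <- pcs$hc[i]
    target_hc <- sample_one(setdiff(seq_len(n_hc), own_hc))
    tgt_pc <- cells$id[cells$type == "PC" & cells$hc == target_hc &
                         cells$mc == pat & !is.na(cells$mc)]
    if (length(tgt_pc) < 4) stop("build error: fewer than 4 PC in target minicolumn")
    chosen <- sample(tgt_pc, 4)
    pre <- c(pre, rep(pcs$id[i], 4))
    post <- c(post, chosen)
    if (spec$lr_target == "MC") {
      cand <- if (spec$interneuron_orientation == "unspecific")
        cells$id[cells$type == "MC" & cells$hc == target_hc]
      else
        cells$id[cells$type == "MC" & cells$hc == target_hc &
                   cells$mc == pat & !is.na(cells$mc)]
      in_pre <- c(in_pre, pcs$id[i]); in_post <- c(in_post, sample_one(cand))
    } else if (spec$lr_target == "BC") {
      cand <- if (spec$interneuron_orientation == "specific")
        cells$id[cells$type == "BC" & cells$hc == target_hc &
                   cells$bc_orient == pat & !is.na(cells$bc_orient)]
      else
        cells$id[cells$type == "BC" & cells$hc == target_hc]
      in_pre <- c(in_pre, pcs$id[i]); in_post <- c(in_post, sample_one(cand))
    }
  }
  ee <- rbind(
    data.frame(pre = pre, post = post, class = "PC-PC_LR", receptor = "AMPA"),
    data.frame(pre = pre, post = post, class = "PC-PC_LR", receptor = "NMDA"))
  if (length(in_pre)) {
    cl <- if (spec$lr_target == "MC") "PC-MC_LR" else "PC-BC_LR"
    ee <- rbind(ee, data.frame(pre = in_pre, post = in_post, class = cl,
                               receptor = "AMPA"))
  }
  ee
}

sample_one <- function(x) if (length(x) == 1) x else sample(x, 1)

#' Variant weight compensation against the Type1 reference
#'
#' When a variant changes interneuron pooling or reroutes long-range
#' terminals, per-connection weights of the affected class groups are
#' rescaled so that the product (cells x incoming projections x weight per
#' connection) matches the Type1 reference built with the same seed. The
#' groups are: excitation onto MC (PC-MC_LO + PC-MC_LR), excitation onto
#' BC (PC-BC + PC-BC_LR), MC output (MC-PC) and BC output (BC-PC); each is
#' scaled by reference edge count / variant edge count.
#'
#' @param network a `column_network` (possibly mid-construction).
#' @param reference optional pre-built Type1 reference network; built on
#'   demand with the same seed when omitted.
#' @return the network with updated `weight_scale` on affected edges.
#' @export
compensate_weights <- function(network, reference = NULL) {
  spec <- network$spec
  if (!isTRUE(spec$compensate) || spec$variant == "Type1") return(network)
  if (is.null(reference)) {
    ref_spec <- spec
    ref_spec$variant <- "Type1"
    ref_spec$lr_target <- "MC"
    ref_spec$lr_dynamics <- "facilitating"
    ref_spec$interneuron_orientation <- "specific"
    set.seed(spec$seed)
    reference <- build_network_raw(ref_spec)
  }
  groups <- list(mc_in = c("PC-MC_LO", "PC-MC_LR"),
                 bc_in = c("PC-BC", "PC-BC_LR"),
                 mc_out = "MC-PC",
                 bc_out = "BC-PC")
  for (g in groups) {
    n_ref <- sum(reference$edges$class %in% g)
    n_var <- sum(network$edges$class %in% g)
    if (n_var == 0) {
      if (n_ref == 0) next
      # group absent in the variant (e.g. no long-range class): nothing to
      # scale, inhibition conservation is handled through the other groups
      next
    }
    if (n_ref == 0) stop("compensation undefined: no reference projections")
    sel <- network$edges$class %in% g
    network$edges$weight_scale[sel] <-
      network$edges$weight_scale[sel] * (n_ref / n_var)
  }
  network
}

#' Assign conduction delays
#'
#' delay = euclidean distance / conduction speed, with a per-connection
#' speed drawn from a Gaussian truncated at 5% of its mean; the ratio of a
#' broad distance distribution to a Gaussian speed yields the familiar
#' right-skewed (gamma-like) delay distribution.
#'
#' @param network a `column_network` with coordinates.
#' @return the network with a `delay_ms` edge column.
#' @export
assign_delays <- function(network) {
  cells <- network$cells
  e <- network$edges
  if (nrow(e) == 0) { network$edges$delay_ms <- numeric(0); return(network) }
  i <- match(e$pre, cells$id); j <- match(e$post, cells$id)
  d_um <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2 +
                 (cells$z[i] - cells$z[j])^2)
  mu <- network$spec$conduction_speed_mean
  sdv <- network$spec$conduction_speed_sd
  v <- rnorm(nrow(e), mu, sdv)
  lo <- 0.05 * mu
  while (any(bad <- v <= lo)) v[bad] <- rnorm(sum(bad), mu, sdv)
  # d in um -> mm = /1000; v in m/s = mm/ms
  network$edges$delay_ms <- pmax(d_um / 1000 / v, 1e-6)
  network
}

#' Write a built network to plain-text files
#'
#' Edge list (pre, post, class, receptor, weight_scale, delay_ms) and cell
#' table as CSV.
#'
#' @param network a `column_network`.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_network_csv <- function(network, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fc <- file.path(dir, "cells.csv")
  fe <- file.path(dir, "edges.csv")
  write.csv(network$cells, fc, row.names = FALSE)
  write.csv(network$edges, fe, row.names = FALSE)
  invisible(c(fc, fe))
}
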