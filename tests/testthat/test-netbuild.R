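# Network construction: counts, scopes, probabilities, long-range rule,
# variants, compensation, delays, determinism.

small_spec <- network_spec(grid = c(2, 2), seed = 7)
small_net <- build_network(small_spec)

test_that("cell counts follow the network layout", {
  cells <- small_net$cells
  expect_equal(nrow(cells), 4 * (6 * (30 + 3 + 3) + 8))
  expect_equal(sum(cells$type == "PC"), 4 * 6 * 30)
  expect_equal(sum(cells$type == "MC"), 4 * 6 * 3)
  expect_equal(sum(cells$type == "VIP"), 4 * 6 * 3)
  expect_equal(sum(cells$type == "BC"), 4 * 8)
  expect_true(all(is.na(cells$mc[cells$type == "BC"])))
})

test_that("no self-connections and no duplicate edges", {
  e <- small_net$edges
  expect_true(all(e$pre != e$post))
  expect_equal(anyDuplicated(e[, c("pre", "post", "class", "receptor")]), 0)
  expect_true(all(e$delay_ms > 0))
})

test_that("local classes respect their scopes", {
  e <- small_net$edges
  cells <- small_net$cells
  hc_of <- cells$hc[match(e$pre, cells$id)]
  hc_post <- cells$hc[match(e$post, cells$id)]
  mc_of <- cells$mc[match(e$pre, cells$id)]
  mc_post <- cells$mc[match(e$post, cells$id)]
  local_mc <- e$class %in% c("PC-PC_LO", "PC-MC_LO", "MC-PC", "VIP-MC")
  expect_true(all(hc_of[local_mc] == hc_post[local_mc]))
  expect_true(all(mc_of[local_mc] == mc_post[local_mc]))
  local_hc <- e$class %in% c("PC-BC", "BC-PC")
  expect_true(all(hc_of[local_hc] == hc_post[local_hc]))
  lr <- grepl("_LR", e$class)
  expect_true(all(hc_of[lr] != hc_post[lr]))
  # long-range edges land on the same pattern index
  lr_pc <- e$class == "PC-PC_LR"
  expect_true(all(mc_of[lr_pc] == mc_post[lr_pc]))
  lr_mc <- e$class == "PC-MC_LR"
  expect_true(all(mc_of[lr_mc] == mc_post[lr_mc]))
})

test_that("realized local connection fractions lie within 3 binomial SE", {
  e <- small_net$edges
  cells <- small_net$cells
  n_mc_groups <- 4 * 6
  trials <- list(
    `PC-PC_LO` = c(p = 0.25, n = n_mc_groups * 30 * 29),
    `PC-MC_LO` = c(p = 0.30, n = n_mc_groups * 30 * 3),
    `MC-PC`    = c(p = 0.80, n = n_mc_groups * 3 * 30),
    `VIP-MC`   = c(p = 0.60, n = n_mc_groups * 3 * 3),
    `PC-BC`    = c(p = 0.70, n = 4 * 180 * 8),
    `BC-PC`    = c(p = 0.70, n = 4 * 8 * 180))
  for (cl in names(trials)) {
    p <- trials[[cl]]["p"]; n <- trials[[cl]]["n"]
    observed <- sum(e$class == cl & e$receptor != "NMDA")
    se <- sqrt(n * p * (1 - p))
    expect_lt(abs(observed - n * p), 3 * se,
              label = paste(cl, "count", observed))
  }
})

test_that("PC-PC contacts carry AMPA and NMDA on the same pairs", {
  e <- small_net$edges
  for (cl in c("PC-PC_LO", "PC-PC_LR")) {
    a <- e[e$class == cl & e$receptor == "AMPA", c("pre", "post")]
    n <- e[e$class == cl & e$receptor == "NMDA", c("pre", "post")]
    expect_equal(a[order(a$pre, a$post), ], n[order(n$pre, n$post), ],
                 ignore_attr = TRUE)
  }
})

test_that("long-range wiring follows the terminal-field rule", {
  e <- small_net$edges
  cells <- small_net$cells
  pcs <- cells$id[cells$type == "PC"]
  lr_pc <- e[e$class == "PC-PC_LR" & e$receptor == "AMPA", ]
  lr_mc <- e[e$class == "PC-MC_LR", ]
  # every PC projects exactly 4 long-range PC contacts and 1 MC terminal
  expect_equal(sort(unique(table(factor(lr_pc$pre, levels = pcs)))), 4)
  expect_true(all(table(factor(lr_mc$pre, levels = pcs)) == 1))
  # the 4 PC targets of each source live in a single minicolumn
  key <- paste(cells$hc, cells$mc)[match(lr_pc$post, cells$id)]
  n_target_mcs <- tapply(key, lr_pc$pre, function(k) length(unique(k)))
  expect_true(all(n_target_mcs == 1))
  # a 1x1 grid has no long-range connections
  net1 <- build_network(network_spec(grid = c(1, 1), seed = 1))
  expect_equal(sum(grepl("_LR", net1$edges$class)), 0)
})

test_that("construction is deterministic given the seed", {
  net_a <- build_network(network_spec(grid = c(2, 2), seed = 7))
  expect_identical(small_net$edges, net_a$edges)
  expect_identical(small_net$cells, net_a$cells)
  net_b <- build_network(network_spec(grid = c(2, 2), seed = 8))
  expect_false(identical(small_net$edges$pre, net_b$edges$pre))
})

test_that("variant flags rewire the long-range interneuron terminal", {
  n5 <- build_network(network_spec(grid = c(2, 2), variant = "Type5", seed = 7))
  expect_equal(sum(n5$edges$class == "PC-MC_LR"), 0)
  expect_equal(sum(n5$edges$class == "PC-BC_LR"), 0)
  expect_gt(sum(n5$edges$class == "PC-PC_LR"), 0)
  n2 <- build_network(network_spec(grid = c(2, 2), variant = "Type2", seed = 7))
  expect_equal(sum(n2$edges$class == "PC-MC_LR"), 0)
  expect_equal(sum(n2$edges$class == "PC-BC_LR"), sum(n2$cells$type == "PC"))
  # Type6: BC orientation specific; long-range lands on the matching BC
  n6 <- build_network(network_spec(grid = c(2, 2), variant = "Type6", seed = 7))
  e6 <- n6$edges[n6$edges$class == "PC-BC_LR", ]
  pat <- n6$cells$mc[match(e6$pre, n6$cells$id)]
  ori <- n6$cells$bc_orient[match(e6$post, n6$cells$id)]
  expect_true(all(pat == ori))
  # Type6 PC-BC/BC-PC restricted to the assigned minicolumn
  ebc <- n6$edges[n6$edges$class == "PC-BC", ]
  expect_true(all(n6$cells$mc[match(ebc$pre, n6$cells$id)] ==
                    n6$cells$bc_orient[match(ebc$post, n6$cells$id)]))
  # Type4: MC classes widen to the hypercolumn (some cross-minicolumn edges)
  n4 <- build_network(network_spec(grid = c(2, 2), variant = "Type4", seed = 7))
  emc <- n4$edges[n4$edges$class == "MC-PC", ]
  mcs <- n4$cells$mc[match(emc$pre, n4$cells$id)]
  mcp <- n4$cells$mc[match(emc$post, n4$cells$id)]
  expect_gt(sum(mcs != mcp), 0)
})

test_that("weight compensation preserves the class-group products", {
  ref <- build_network(network_spec(grid = c(2, 2), variant = "Type1", seed = 7))
  for (variant in c("Type4", "Type5", "Type2")) {
    v <- build_network(network_spec(grid = c(2, 2), variant = variant, seed = 7))
    groups <- list(c("PC-MC_LO", "PC-MC_LR"), c("PC-BC", "PC-BC_LR"),
                   "MC-PC", "BC-PC")
    for (g in groups) {
      n_ref <- sum(ref$edges$class %in% g)
      sel <- v$edges$class %in% g
      if (!any(sel)) next
      # sum of per-connection weights equals the reference edge count
      expect_equal(sum(v$edges$weight_scale[sel]), n_ref, tolerance = 1e-9,
                   label = paste(variant, paste(g, collapse = "+")))
    }
  }
  # Type1 vs Type1: identity
  expect_true(all(ref$edges$weight_scale == 1))
})

test_that("delays are distance over truncated-Gaussian speed and right-skewed", {
  e <- small_net$edges
  cells <- small_net$cells
  i <- match(e$pre, cells$id); j <- match(e$post, cells$id)
  d_mm <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2 +
                 (cells$z[i] - cells$z[j])^2) / 1000
  v_imp <- d_mm / e$delay_ms   # implied speed, m/s
  expect_true(all(v_imp > 0.05 * 0.3 - 1e-9))
  expect_lt(abs(mean(v_imp) - 0.3), 3 * sd(v_imp) / sqrt(length(v_imp)))
  # skewness of the delay distribution > 0
  z <- (e$delay_ms - mean(e$delay_ms)) / sd(e$delay_ms)
  expect_gt(mean(z^3), 0)
  # sd = 0 gives one delay per distance
  sp0 <- network_spec(grid = c(1, 1), seed = 3, conduction_speed_sd = 0)
  n0 <- build_network(sp0)
  i0 <- match(n0$edges$pre, n0$cells$id); j0 <- match(n0$edges$post, n0$cells$id)
  d0 <- sqrt((n0$cells$x[i0] - n0$cells$x[j0])^2 +
               (n0$cells$y[i0] - n0$cells$y[j0])^2 +
               (n0$cells$z[i0] - n0$cells$z[j0])^2) / 1000
  expect_equal(n0$edges$delay_ms, d0 / 0.3, tolerance = 1e-9)
  # 1 mm at exactly 0.3 m/s is 3.33 ms
  expect_equal(1 / 0.3, 3.333, tolerance = 1e-3)
})

test_that("expected in/out-degrees match the published probabilities", {
  e <- small_net$edges
  cells <- small_net$cells
  pcs <- cells$id[cells$type == "PC"]
  indeg <- table(factor(e$post[e$class == "PC-PC_LO" &
                                 e$receptor == "AMPA"], levels = pcs))
  expect_equal(mean(indeg), 0.25 * 29, tolerance = 0.05)
  bcs <- cells$id[cells$type == "BC"]
  outdeg <- table(factor(e$pre[e$class == "BC-PC"], levels = bcs))
  expect_equal(mean(outdeg), 0.70 * 180, tolerance = 0.05)
})

test_that("network CSV export round-trips", {
  dir <- tempfile()
  files <- write_network_csv(small_net, dir)
  expect_true(all(file.exists(files)))
  e2 <- read.csv(file.path(dir, "edges.csv"))
  expect_equal(nrow(e2), nrow(small_net$edges))
  unlink(dir, recursive = TRUE)
})
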