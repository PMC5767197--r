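# Charge-scaling corrections and the scaling-factor grid.

test_that("the four-term scaling combination behaves as specified", {
  tab <- tibble::tibble(
    ligand = rep(c("L1", "L2"), each = 2),
    environment = rep(c("free", "bound"), 2),
    factor = 0.7,
    dg_scaled = c(1.0, 1.5, 0.5, 2.0)
  )
  expect_equal(scaling_correction(tab, "L1", "L2", 0.7),
               1.0 + 2.0 - 1.5 - 0.5)
  expect_equal(scaling_correction(tab, "L1", "L1", 0.7), 0)

  # factor-1 entries are all zero, so the correction vanishes
  truth <- generate_ground_truth(4, seed = 1)
  sim <- simulate_scaling_table(truth, factors = c(1, 0.7), seed = 1)
  expect_equal(scaling_correction(sim, "L01", "L02", 1), 0)

  expect_error(scaling_correction(tab, "L1", "L3", 0.7), "L3",
               class = "fepnet_missing_data")
})

test_that("corrections are antisymmetric for any table", {
  truth <- generate_ground_truth(6, charged_fraction = 0.5, seed = 3)
  tab <- simulate_scaling_table(truth, factors = c(1, 0.7, 0.5),
                                polarisation_strength = 2, seed = 3)
  ligs <- truth$ligands$ligand
  for (i in 1:5) {
    pair <- sample(ligs, 2)
    for (f in c(0.7, 0.5)) {
      expect_equal(scaling_correction(tab, pair[1], pair[2], f),
                   -scaling_correction(tab, pair[2], pair[1], f),
                   tolerance = 1e-12)
    }
  }
})

test_that("edge corrections pick factors from the charge rule", {
  truth <- generate_ground_truth(4, charged_fraction = 0.25, seed = 5)
  charges <- setNames(truth$ligands$charge, truth$ligands$ligand)
  charged <- names(charges)[charges == -1L][1]
  neutral <- names(charges)[charges == 0L]
  tab <- simulate_scaling_table(truth, factors = c(1, 0.7, 0.5), seed = 5)

  edges <- tibble::tibble(
    node_a = paste0(c(neutral[1], neutral[1]), "@a"),
    node_b = paste0(c(neutral[2], charged), "@a"),
    mean_ddg = c(1, 2), std_err = 0.1
  )
  out <- apply_corrections(edges, tab, charges)
  expect_equal(out$factor_used, c(0.7, 0.5))
  expect_equal(out$mean_ddg, edges$mean_ddg + out$correction)

  # an all-zero table is a no-op
  zero <- simulate_scaling_table(truth, factors = c(1, 0.7, 0.5),
                                 polarisation_strength = 0, seed = 5)
  same <- apply_corrections(edges, zero, charges)
  expect_equal(same$mean_ddg, edges$mean_ddg)
  expect_true(all(same$correction == 0))
})

test_that("corrections telescope around cycles at a single factor", {
  truth <- generate_ground_truth(5, seed = 6)
  tab <- simulate_scaling_table(truth, factors = c(1, 0.7, 0.5), seed = 6)
  cyc <- c("L01", "L02", "L03", "L04", "L01")
  total <- sum(vapply(seq_len(4), function(i) {
    scaling_correction(tab, cyc[i], cyc[i + 1], 0.7)
  }, numeric(1)))
  expect_equal(total, 0, tolerance = 1e-12)

  # under the mixed 0.7/0.5 rule the cancellation can fail: construct a
  # triangle where one edge changes charge
  truth2 <- generate_ground_truth(3, charged_fraction = 1 / 3, seed = 7)
  tab2 <- simulate_scaling_table(truth2, factors = c(1, 0.7, 0.5),
                                 polarisation_strength = 2, seed = 7)
  charges2 <- setNames(truth2$ligands$charge, truth2$ligands$ligand)
  ligs <- truth2$ligands$ligand
  edges2 <- tibble::tibble(
    node_a = paste0(c(ligs[1], ligs[1], ligs[2]), "@a"),
    node_b = paste0(c(ligs[2], ligs[3], ligs[3]), "@a"),
    mean_ddg = 0, std_err = 0.1
  )
  corr <- apply_corrections(edges2, tab2, charges2)
  # oriented sum around the triangle 1 -> 2 -> 3 -> 1
  around <- corr$correction[1] + corr$correction[3] - corr$correction[2]
  expect_gt(abs(around), 1e-6)
})

test_that("the grid report scores factors and flags the MUE optimum", {
  est <- tibble::tibble(ligand = c("A", "B", "C", "D"),
                        ddg_vs_ref = c(0, -1, -2, 1), err = 0)
  experimental <- tibble::tibble(ligand = est$ligand,
                                 exp_ddg = est$ddg_vs_ref)
  grid <- scaling_grid_report(list(`1` = est), experimental,
                              n_boot = 50, seed = 1)
  expect_equal(nrow(grid), 1)
  expect_equal(grid$r_mean, 1)
  expect_equal(grid$mue_mean, 0)
  expect_true(grid$best_mue && grid$best_r)
})

test_that("a factor-0.7 polarisation mechanism is recovered by the grid", {
  grids <- lapply(1:3, function(seed) {
    truth <- generate_ground_truth(10, dg_span = 5, charged_fraction = 0.2,
                                   seed = seed)
    charges <- setNames(truth$ligands$charge, truth$ligands$ligand)
    factors <- seq(1, 0.5, by = -0.1)
    tab <- simulate_scaling_table(truth, factors = factors,
                                  polarisation_strength = 1.5, seed = seed)
    bias <- scaling_ligand_bias(tab, factor = 0.7)
    topo <- generate_topology(truth, extra_chords = 3, seed = seed)
    noise <- noise_model(edge_sigma = 0.1, n_repeats = 3, seed = seed)
    m <- simulate_edges(truth, topo, noise, ligand_bias = bias)
    edges <- aggregate_edges(m)
    uniform_rule <- function(f) charge_rule(f, f)
    by_factor <- lapply(factors, function(f) {
      corrected <- apply_corrections(edges, tab, charges,
                                     rule = uniform_rule(f))
      net <- build_network(corrected, charges = charges)
      relative_free_energies(net, truth$reference)
    })
    names(by_factor) <- factors
    exp_tbl <- tibble::tibble(
      ligand = truth$ligands$ligand,
      exp_ddg = truth$ligands$true_dg -
        truth$ligands$true_dg[truth$ligands$ligand == truth$reference]
    )
    scaling_grid_report(by_factor, exp_tbl, n_boot = 200, seed = seed)
  })
  avg <- dplyr::bind_rows(grids) |>
    dplyr::group_by(factor) |>
    dplyr::summarise(mue = mean(mue_mean))
  expect_equal(avg$factor[which.min(avg$mue)], 0.7)
})
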