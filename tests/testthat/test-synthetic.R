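# Synthetic-study generators: determinism, stated contracts, and the
# statistical structure downstream stages rely on.

test_that("ground truth generation is deterministic and honours its contracts", {
  t1 <- generate_ground_truth(5, dg_span = 3, charged_fraction = 0,
                              max_modes = 1, seed = 1)
  t2 <- generate_ground_truth(5, dg_span = 3, charged_fraction = 0,
                              max_modes = 1, seed = 1)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$ligands), 5)
  expect_true(all(t1$ligands$charge == 0))
  expect_true(all(table(t1$nodes$ligand) == 1))

  # charged count is the ceiling of the fraction
  t3 <- generate_ground_truth(10, charged_fraction = 0.2, seed = 3)
  expect_equal(sum(t3$ligands$charge == -1L), 2)

  # span bound: tiny span collapses all pairwise differences
  t4 <- generate_ground_truth(3, dg_span = 1e-4, seed = 4)
  expect_lt(diff(range(t4$ligands$true_dg)), 1e-4 + 1e-12)

  # mode counts stay within 1..max_modes
  t5 <- generate_ground_truth(20, max_modes = 3, seed = 5)
  counts <- table(t5$nodes$ligand)
  expect_true(all(counts >= 1 & counts <= 3))

  expect_error(generate_ground_truth(2), "n_ligands")
  expect_error(generate_ground_truth(5, dg_span = 0), "dg_span")
})

test_that("mode free energies are Boltzmann-consistent with ligand truth", {
  truth <- generate_ground_truth(8, max_modes = 3, seed = 11)
  kt <- kT(truth$temperature)
  recombined <- truth$nodes |>
    dplyr::group_by(ligand) |>
    dplyr::summarise(dg = {
      m <- min(dg_node); m - kt * log(sum(exp(-(dg_node - m) / kt)))
    })
  expect_equal(recombined$dg, truth$ligands$true_dg, tolerance = 1e-12)
})

test_that("topology is a connected tree plus the requested chords", {
  truth <- generate_ground_truth(5, seed = 1)
  tree <- generate_topology(truth, extra_chords = 0, seed = 1)
  expect_equal(nrow(tree), 4) # spanning tree on 5 nodes

  with_chords <- generate_topology(truth, extra_chords = 2, seed = 1)
  expect_equal(nrow(with_chords), 6)
  # cycle-space dimension = E - V + components
  edges <- with_chords |>
    dplyr::mutate(mean_ddg = 0, std_err = 0)
  net <- build_network(edges)
  expect_equal(glance(net)$cycle_space_dim, 2)
  expect_equal(glance(net)$n_components, 1)

  # connectivity holds for multi-mode node sets too
  truth2 <- generate_ground_truth(7, max_modes = 3, seed = 2)
  topo2 <- generate_topology(truth2, extra_chords = 5, seed = 2)
  net2 <- build_network(dplyr::mutate(topo2, mean_ddg = 0, std_err = 0))
  expect_equal(dplyr::n_distinct(connectivity_report(net2)$component), 1)
  expect_true(all(topo2$node_a != topo2$node_b))
  expect_false(anyDuplicated(paste(topo2$node_a, topo2$node_b)) > 0)
})

test_that("edge simulation is exact at zero noise and counts records correctly", {
  truth <- generate_ground_truth(5, seed = 1)
  topo <- generate_topology(truth, extra_chords = 1, seed = 1)

  m <- simulate_edges(truth, topo, noise_model(edge_sigma = 0, seed = 1))
  dg <- setNames(truth$nodes$dg_node, truth$nodes$node)
  fwd <- dplyr::filter(m, direction == "forward")
  expected <- dg[paste0(fwd$ligand_to, "@", fwd$mode_to)] -
    dg[paste0(fwd$ligand_from, "@", fwd$mode_from)]
  expect_equal(fwd$ddg, unname(expected), tolerance = 1e-14)

  topo6 <- generate_topology(truth, extra_chords = 2, seed = 1) # 6 edges
  m3 <- simulate_edges(truth, topo6,
                       noise_model(edge_sigma = 0.1, n_repeats = 3, seed = 2))
  expect_equal(nrow(m3), 6 * 3 * 2)

  # determinism
  m3b <- simulate_edges(truth, topo6,
                        noise_model(edge_sigma = 0.1, n_repeats = 3, seed = 2))
  expect_identical(m3, m3b)
})

test_that("charge-change bias shifts the forward mean by the stated offset", {
  truth <- generate_ground_truth(3, charged_fraction = 1 / 3, seed = 7)
  q <- setNames(truth$ligands$charge, truth$ligands$ligand)
  charged <- names(q)[q == -1L][1]
  neutral <- names(q)[q == 0L][1]
  topo <- tibble::tibble(node_a = paste0(neutral, "@a"),
                         node_b = paste0(charged, "@a"))
  noise <- noise_model(edge_sigma = 0.5, n_repeats = 1000,
                       charge_change_bias = 5, seed = 9)
  m <- simulate_edges(truth, topo, noise)
  dg <- setNames(truth$nodes$dg_node, truth$nodes$node)
  true_fwd <- dg[[topo$node_b]] - dg[[topo$node_a]]
  fwd <- dplyr::filter(m, direction == "forward")$ddg
  se <- 0.5 / sqrt(1000)
  expect_lt(abs(mean(fwd) - (true_fwd + 5)), 3 * se)
})

test_that("gradient generator integrates to its target and honours drift", {
  g <- simulate_gradients(2.5, n_lambda = 7, n_samples = 40,
                          noise_sigma = 0, seed = 1)
  expect_equal(ti_estimate(g), 2.5, tolerance = 1e-12)

  # a drifting series raises the mean of late samples in every window
  gd <- simulate_gradients(0, n_lambda = 2, n_samples = 400,
                           noise_sigma = 0, drift = 2, seed = 1)
  w <- dplyr::filter(gd, lambda == 0)
  expect_gt(mean(w$dudl[201:400]), mean(w$dudl[1:200]))

  expect_error(simulate_gradients(1, n_lambda = 1), "n_lambda")
  expect_error(simulate_gradients(1, ar1_rho = 1), "ar1_rho")
})

test_that("IC50 simulation inverts the free energy conversion", {
  truth <- generate_ground_truth(6, dg_span = 4, seed = 3)
  ic50 <- simulate_experiment(truth, noise_model(exp_sigma = 0, seed = 3))
  expect_true(all(ic50$ic50 > 0))
  back <- experimental_ddg(ic50, truth$reference)
  ref_dg <- truth$ligands$true_dg[truth$ligands$ligand == truth$reference]
  expect_equal(back$exp_ddg, truth$ligands$true_dg - ref_dg,
               tolerance = 1e-12)
  # reference ligand maps to IC50 ratio 1 and ddG 0
  expect_equal(ic50$ic50[ic50$ligand == truth$reference], 1)
})

test_that("experimental noise propagates to ~exp_sigma RMS on the ddG scale", {
  truth <- generate_ground_truth(200, dg_span = 6, seed = 5)
  ic50 <- simulate_experiment(truth, noise_model(exp_sigma = 0.4, seed = 5))
  back <- experimental_ddg(ic50, truth$reference)
  ref_dg <- truth$ligands$true_dg[truth$ligands$ligand == truth$reference]
  resid <- back$exp_ddg - (truth$ligands$true_dg - ref_dg)
  resid <- resid[back$ligand != truth$reference]
  expect_lt(abs(sqrt(mean(resid^2)) - 0.4), 0.15 * 0.4)
})

test_that("scaling tables are zero at factor one and grow as charges shrink", {
  truth <- generate_ground_truth(6, charged_fraction = 0.5, seed = 2)
  tab <- simulate_scaling_table(truth, factors = c(1, 0.7, 0.5),
                                polarisation_strength = 1, seed = 2)
  expect_true(all(tab$dg_scaled[tab$factor == 1] == 0))

  by_factor <- tab |>
    tidyr::pivot_wider(id_cols = c(ligand, environment),
                       names_from = factor, values_from = dg_scaled)
  expect_true(all(abs(by_factor$`0.5`) >= abs(by_factor$`0.7`)))

  zero <- simulate_scaling_table(truth, factors = c(1, 0.7),
                                 polarisation_strength = 0, seed = 2)
  expect_true(all(zero$dg_scaled == 0))
  expect_error(simulate_scaling_table(truth, factors = numeric(0)),
               "non-empty")
})
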