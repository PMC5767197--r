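# Simple-path enumeration, weighted combination, binding-mode averaging
# and cycle closure.

test_that("simple paths are enumerated exhaustively and deterministically", {
  chain <- build_network(tibble::tibble(
    node_a = c("A@a", "B@a"), node_b = c("B@a", "C@a"),
    mean_ddg = 1, std_err = 0.1
  ))
  expect_equal(enumerate_simple_paths(chain, "A@a", "C@a"),
               list(c("A@a", "B@a", "C@a")))

  tri <- build_network(triangle_edges())
  expect_length(enumerate_simple_paths(tri, "A@a", "C@a"), 2)

  # complete graph on 4 nodes: 1 direct + 2 one-hop + 2 two-hop paths
  nodes <- c("A@a", "B@a", "C@a", "D@a")
  pairs <- utils::combn(nodes, 2)
  k4 <- build_network(tibble::tibble(
    node_a = pairs[1, ], node_b = pairs[2, ], mean_ddg = 1, std_err = 0.1
  ))
  paths <- enumerate_simple_paths(k4, "A@a", "B@a")
  expect_length(paths, 5)
  # shortest first, lexicographic within a length class
  expect_equal(lengths(paths), c(2L, 3L, 3L, 4L, 4L))
  expect_equal(paths[[1]], c("A@a", "B@a"))
  expect_equal(paths[[2]], c("A@a", "C@a", "B@a"))

  # caps truncate but keep the shortest paths
  expect_length(enumerate_simple_paths(k4, "A@a", "B@a", max_paths = 3), 3)
  expect_length(enumerate_simple_paths(k4, "A@a", "B@a", max_length = 3), 3)

  # disconnected pair: empty list, not an error
  island <- build_network(dplyr::bind_rows(
    triangle_edges(),
    tibble::tibble(node_a = "X@a", node_b = "Y@a", mean_ddg = 0, std_err = 0)
  ))
  expect_length(enumerate_simple_paths(island, "A@a", "X@a"), 0)
})

test_that("enumeration matches the permutation oracle on small graphs", {
  for (seed in 1:12) {
    n <- sample(3:6, 1)
    g <- random_connected_graph(n, extra = sample(0:3, 1), seed = seed)
    net <- build_network(g)
    st <- sample(net$nodes, 2)
    got <- enumerate_simple_paths(net, st[1], st[2])
    want <- oracle_simple_paths(net$nodes, g$node_a, g$node_b, st[1], st[2])
    key <- function(p) paste(p, collapse = ">")
    expect_setequal(vapply(got, key, character(1)),
                    vapply(want, key, character(1)))
  }
})

test_that("path free energies sum edges and errors in quadrature", {
  net <- build_network(tibble::tibble(
    node_a = c("A@a", "B@a"), node_b = c("B@a", "C@a"),
    mean_ddg = c(1.0, 0.5), std_err = c(0.1, 0.2)
  ))
  est <- path_estimate(net, c("A@a", "B@a", "C@a"))
  expect_equal(est$dg, 1.5)
  expect_equal(est$err, sqrt(0.05), tolerance = 1e-12)

  # reversal negates dg, preserves err
  rev_est <- path_estimate(net, c("C@a", "B@a", "A@a"))
  expect_equal(rev_est$dg, -1.5)
  expect_equal(rev_est$err, est$err)

  single <- path_estimate(net, c("A@a", "B@a"))
  expect_equal(single$dg, 1.0)
  expect_equal(single$err, 0.1)

  zero_err <- build_network(triangle_edges(err = c(0, 0, 0)))
  expect_equal(path_estimate(zero_err, c("A@a", "B@a", "C@a"))$err, 0)

  expect_error(path_estimate(net, c("A@a", "C@a")), "No edge")
})

test_that("inverse-error weighting combines paths as a proper weighted mean", {
  one <- combine_paths(tibble::tibble(dg = 1.5, err = 0.22))
  expect_equal(one$ddg, 1.5)
  expect_equal(one$err, 0.22)

  sym <- combine_paths(tibble::tibble(dg = c(1, 2), err = c(0.3, 0.3)))
  expect_equal(sym$ddg, 1.5)

  two <- combine_paths(tibble::tibble(dg = c(1, 2), err = c(0.1, 0.3)))
  expect_equal(two$ddg, 0.75 * 1 + 0.25 * 2, tolerance = 1e-12)
  expect_equal(two$err, sqrt(0.75^2 * 0.01 + 0.25^2 * 0.09),
               tolerance = 1e-12)
  expect_equal(two$err, 0.1060660, tolerance = 1e-6)

  expect_error(combine_paths(tibble::tibble(dg = numeric(0),
                                            err = numeric(0))),
               "At least one")
})

test_that("normalized combination is scale-consistent and range-bounded", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:6, 1)
    paths <- tibble::tibble(dg = rnorm(k, 0, 2), err = runif(k, 0.01, 1))
    base <- combine_paths(paths)
    scaled <- combine_paths(dplyr::mutate(paths, err = err * 7.3))
    expect_equal(scaled$ddg, base$ddg, tolerance = 1e-12)
    expect_gte(base$ddg, min(paths$dg) - 1e-12)
    expect_lte(base$ddg, max(paths$dg) + 1e-12)
  }
})

test_that("the literal audit mode reproduces the printed formulas verbatim", {
  paths <- tibble::tibble(dg = c(1, 2), err = c(0.1, 0.3))
  lit <- combine_paths(paths, mode = "paper_literal",
                       err_mode = "paper_literal")
  omega <- sum(1 / paths$err)
  expect_equal(lit$ddg, sum(omega * paths$dg / paths$err), tolerance = 1e-12)
  expect_equal(lit$err, sqrt(sum(omega * paths$err)), tolerance = 1e-12)
})

test_that("binding-mode exponential averaging follows Boltzmann statistics", {
  kt <- kT(298)

  one <- combine_binding_modes(-2.3, 0.15)
  expect_equal(one$ddg, -2.3)
  expect_equal(one$err, 0.15)

  # two identical modes shift by exactly -kT log 2
  two <- combine_binding_modes(c(-1, -1), c(0.1, 0.2))
  expect_equal(two$ddg, -1 - kt * log(2), tolerance = 1e-12)
  expect_equal(two$ddg, -1.41047, tolerance = 1e-4)
  expect_equal(two$err, 0.1) # dominant mode's error

  # a hopeless mode contributes nothing
  dom <- combine_binding_modes(c(0, 100), c(0.3, 0.9))
  expect_equal(dom$ddg, 0, tolerance = 1e-10)
  expect_equal(dom$err, 0.3)

  # bounds: min - kT log N <= result <= min, over random mode sets
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(1:5, 1)
    g <- rnorm(n, 0, 3)
    res <- combine_binding_modes(g, rep(0.1, n))
    expect_lte(res$ddg, min(g) + 1e-12)
    expect_gte(res$ddg, min(g) - kt * log(n) - 1e-12)
  }
})

test_that("zero-noise networks reproduce ground truth exactly", {
  # consistent triangle from truth {A: 0, B: -1, C: -2.5}
  net <- build_network(tibble::tibble(
    node_a = c("A@a", "A@a", "B@a"), node_b = c("B@a", "C@a", "C@a"),
    mean_ddg = c(-1, -2.5, -1.5), std_err = 0
  ))
  est <- relative_free_energies(net, "A")
  expect_equal(est$ddg_vs_ref[est$ligand == "B"], -1, tolerance = 1e-12)
  expect_equal(est$ddg_vs_ref[est$ligand == "C"], -2.5, tolerance = 1e-12)
  expect_equal(est$ddg_vs_ref[est$ligand == "A"], 0)
  expect_equal(est$err[est$ligand == "A"], 0)

  # re-referencing shifts all values by a constant in the noiseless case
  est_b <- relative_free_energies(net, "B")
  shift <- est$ddg_vs_ref - est_b$ddg_vs_ref
  expect_equal(diff(range(shift)), 0, tolerance = 1e-12)
})

test_that("tree networks reduce to the unique path sum", {
  chain <- build_network(tibble::tibble(
    node_a = c("A@a", "B@a", "C@a"), node_b = c("B@a", "C@a", "D@a"),
    mean_ddg = c(0.5, -1.2, 2.0), std_err = c(0.1, 0.2, 0.3)
  ))
  est <- relative_free_energies(chain, "A")
  expect_equal(est$ddg_vs_ref[est$ligand == "D"], 0.5 - 1.2 + 2.0,
               tolerance = 1e-12)
  expect_equal(est$err[est$ligand == "D"], sqrt(0.01 + 0.04 + 0.09),
               tolerance = 1e-12)
  expect_true(all(est$n_paths == 1))
})

test_that("per-ligand estimates match the brute-force oracle on noisy graphs", {
  for (seed in 1:10) {
    n <- sample(4:6, 1)
    g <- random_connected_graph(n, extra = sample(1:3, 1), seed = 100 + seed)
    net <- build_network(g)
    ref <- net$nodes[1]
    est <- relative_free_energies(net, ref)
    for (nd in net$nodes) {
      want_paths <- oracle_simple_paths(net$nodes, g$node_a, g$node_b,
                                        nd, ref)
      if (nd == ref) next
      want <- oracle_combine(net$w, net$eps, want_paths)
      got <- est[est$ligand == sub("@.*", "", nd), ]
      expect_equal(got$ddg_vs_ref, -want$ddg, tolerance = 1e-12)
      expect_equal(got$err, want$err, tolerance = 1e-12)
      expect_equal(got$n_paths, length(want_paths))
    }
  }
})

test_that("multi-mode ligands are collapsed through exponential averaging", {
  # ligand B has two modes hanging off A; the combined estimate must be the
  # Boltzmann average of the two independent mode estimates
  net <- build_network(tibble::tibble(
    node_a = c("A@a", "A@a"), node_b = c("B@a", "B@b"),
    mean_ddg = c(-1.0, -0.5), std_err = c(0.1, 0.2)
  ))
  est <- relative_free_energies(net, "A")
  kt <- kT(298)
  want <- -kt * log(exp(1.0 / kt) + exp(0.5 / kt))
  expect_equal(est$ddg_vs_ref[est$ligand == "B"], want, tolerance = 1e-12)
  expect_equal(est$modes_combined[est$ligand == "B"], 2)
  expect_equal(est$err[est$ligand == "B"], 0.1) # dominant mode is B@a
})

test_that("cycle closures measure network inconsistency over a cycle basis", {
  # consistent triangle: closure machine-zero
  consistent <- build_network(tibble::tibble(
    node_a = c("A@a", "A@a", "B@a"), node_b = c("B@a", "C@a", "C@a"),
    mean_ddg = c(1, 2.5, 1.5), std_err = 0.1
  ))
  rep0 <- cycle_closure_report(consistent)
  expect_equal(nrow(rep0), 1)
  expect_lt(rep0$closure, 1e-12)
  expect_false(rep0$flagged)

  # a -> b -> c vs direct a -> c disagrees by 0.5
  off <- build_network(triangle_edges(w_ab = 1, w_bc = 1, w_ac = 2.5))
  rep1 <- cycle_closure_report(off, threshold = 0.3)
  expect_equal(rep1$closure, 0.5, tolerance = 1e-12)
  expect_true(rep1$flagged)

  # trees have no cycles to close
  tree <- build_network(tibble::tibble(
    node_a = c("A@a", "B@a"), node_b = c("B@a", "C@a"),
    mean_ddg = 1, std_err = 0.1
  ))
  expect_equal(nrow(cycle_closure_report(tree)), 0)

  # basis covers the full cycle space dimension
  g <- random_connected_graph(6, extra = 3, seed = 5)
  net <- build_network(g)
  expect_equal(nrow(cycle_closure_report(net)),
               glance(net)$cycle_space_dim)
})
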