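# Shared fixtures and independent oracles.
#
# The oracles below deliberately avoid every package function and igraph:
# paths are found by exhaustive permutation search and combined with a
# literal transcription of the weighting formulas, so they can certify the
# production code.

# triangle over single-mode ligands A, B, C with configurable weights
triangle_edges <- function(w_ab = 1, w_ac = 2.5, w_bc = 1.5,
                           err = c(0.1, 0.1, 0.1)) {
  tibble::tibble(
    node_a = c("A@a", "A@a", "B@a"),
    node_b = c("B@a", "C@a", "C@a"),
    mean_ddg = c(w_ab, w_ac, w_bc),
    std_err = err
  )
}

# exhaustive simple-path search: try every ordered subset of intermediate
# vertices between s and t, keep sequences whose consecutive pairs all have
# an edge
oracle_simple_paths <- function(nodes, edge_a, edge_b, s, t) {
  has_edge <- matrix(FALSE, length(nodes), length(nodes),
                     dimnames = list(nodes, nodes))
  for (i in seq_along(edge_a)) {
    has_edge[edge_a[i], edge_b[i]] <- TRUE
    has_edge[edge_b[i], edge_a[i]] <- TRUE
  }
  mid <- setdiff(nodes, c(s, t))
  found <- list()
  add_perms <- function(subset) {
    if (length(subset) == 0) {
      perms <- list(character(0))
    } else {
      idx <- permutations_of(length(subset))
      perms <- lapply(seq_len(nrow(idx)), function(r) subset[idx[r, ]])
    }
    for (p in perms) {
      path <- c(s, p, t)
      ok <- all(vapply(seq_len(length(path) - 1),
                       function(i) has_edge[path[i], path[i + 1]],
                       logical(1)))
      if (ok) found[[length(found) + 1]] <<- path
    }
  }
  subsets <- list(character(0))
  for (k in seq_along(mid)) {
    combos <- utils::combn(mid, k, simplify = FALSE)
    subsets <- c(subsets, combos)
  }
  for (sub in subsets) add_perms(sub)
  found
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- (1:n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# literal reimplementation of the inverse-error weighted path combination
oracle_combine <- function(w, eps, paths, err_floor = 1e-6) {
  dg <- vapply(paths, function(p) {
    sum(vapply(seq_len(length(p) - 1),
               function(i) w[p[i], p[i + 1]], numeric(1)))
  }, numeric(1))
  e <- vapply(paths, function(p) {
    sqrt(sum(vapply(seq_len(length(p) - 1),
                    function(i) eps[p[i], p[i + 1]]^2, numeric(1))))
  }, numeric(1))
  e <- pmax(e, err_floor)
  u <- 1 / e
  wt <- u / sum(u)
  list(ddg = sum(wt * dg), err = sqrt(sum(wt^2 * e^2)))
}

# random connected graph on n nodes: random spanning chain + random chords,
# built without igraph
random_connected_graph <- function(n, extra = 2, seed = 1) {
  set.seed(seed)
  nodes <- paste0(LETTERS[1:n], "@a")
  order <- sample(nodes)
  edge_a <- order[-n]
  edge_b <- order[-1]
  all_pairs <- utils::combn(nodes, 2)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  used <- key(edge_a, edge_b)
  free <- which(!key(all_pairs[1, ], all_pairs[2, ]) %in% used)
  if (extra > 0 && length(free) > 0) {
    pick <- free[sample.int(length(free), min(extra, length(free)))]
    edge_a <- c(edge_a, all_pairs[1, pick])
    edge_b <- c(edge_b, all_pairs[2, pick])
  }
  a <- pmin(edge_a, edge_b)
  b <- pmax(edge_a, edge_b)
  tibble::tibble(
    node_a = a, node_b = b,
    mean_ddg = round(rnorm(length(a)), 3),
    std_err = round(runif(length(a), 0.05, 0.5), 3)
  )
}

# study conditions used by the recovery checks
recovery_study <- function(seed, n_ligands = 10, edge_sigma = 0.3,
                           n_repeats = 3, extra_chords = 3) {
  truth <- generate_ground_truth(n_ligands, dg_span = 5, seed = seed)
  topo <- generate_topology(truth, extra_chords = extra_chords, seed = seed)
  noise <- noise_model(edge_sigma = edge_sigma, n_repeats = n_repeats,
                       seed = seed)
  m <- simulate_edges(truth, topo, noise)
  edges <- suppressWarnings(aggregate_edges(m))
  net <- build_network(edges,
                       charges = setNames(truth$ligands$charge,
                                          truth$ligands$ligand))
  est <- relative_free_energies(net, truth$reference)
  truth_vs_ref <- truth$ligands$true_dg -
    truth$ligands$true_dg[truth$ligands$ligand == truth$reference]
  list(truth = truth, estimates = est,
       joined = dplyr::inner_join(
         est,
         tibble::tibble(ligand = truth$ligands$ligand,
                        true_ddg = truth_vs_ref),
         by = "ligand"
       ))
}
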