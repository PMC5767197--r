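# Per-ligand relative binding free energies by simple-path combination.
#
# Every simple path from a ligand to the reference gives an independent
# (though correlated) estimate: the sum of edge free energies, with a
# root-sum-square error. Paths are combined by a normalized inverse-error
# weighted mean so that more precise paths contribute more; a literal
# transcription of the originally printed (dimensionally inconsistent)
# formulas is retained as an audit mode.

#' Enumerate simple paths between two nodes
#'
#' Returns every simple path (no repeated vertex) from `source` to `target`
#' using only existing network edges, in deterministic order: shortest
#' first, ties broken lexicographically. The enumeration is exhaustive
#' whenever the true path count does not exceed `max_paths` and all path
#' lengths are within `max_length`; otherwise the first `max_paths` paths
#' in that order are returned.
#'
#' @param net A `perturbation_network`.
#' @param source,target Node identifiers (ligand@mode).
#' @param max_paths Cap on the number of returned paths.
#' @param max_length Maximum number of vertices per path (default: all
#'   nodes, i.e. no restriction).
#' @return A list of character vectors; empty when the pair is
#'   disconnected. `source == target` yields the trivial single-vertex path.
#' @examples
#' edges <- tibble::tibble(node_a = c("A@a", "A@a", "B@a"),
#'                         node_b = c("B@a", "C@a", "C@a"),
#'                         mean_ddg = c(1, 2.5, 1.5), std_err = 0.1)
#' net <- build_network(edges)
#' enumerate_simple_paths(net, "A@a", "C@a")
#' @export
enumerate_simple_paths <- function(net, source, target,
                                   max_paths = 10000, max_length = NULL) {
  stopifnot(inherits(net, "perturbation_network"))
  if (!source %in% net$nodes || !target %in% net$nodes) {
    abort("`source` and `target` must be network nodes.")
  }
  if (max_paths < 1) abort("`max_paths` must be >= 1.")
  if (source == target) return(list(source))
  max_length <- max_length %||% length(net$nodes)

  g <- as_igraph(net)
  paths <- igraph::all_simple_paths(g, from = source, to = target,
                                    cutoff = max_length - 1)
  if (length(paths) == 0) return(list())
  paths <- purrr::map(paths, ~ igraph::as_ids(.x))
  # deterministic order: shortest first, then lexicographic on the vertex seq
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  ord <- order(lengths(paths), keys)
  head(paths[ord], max_paths)
}

#' Free energy and error along one simple path
#'
#' The path free energy is the oriented sum of adjacency entries; the path
#' error is the root-sum-square of the edge errors. Reversing the path
#' negates the free energy and preserves the error.
#'
#' @param net A `perturbation_network`.
#' @param path Character vector of consecutive node identifiers.
#' @return A one-row tibble with `dg`, `err`, `length` (edge count).
#' @export
path_estimate <- function(net, path) {
  stopifnot(inherits(net, "perturbation_network"))
  if (length(path) < 1 || !all(path %in% net$nodes)) {
    abort("`path` must be a sequence of network nodes.")
  }
  if (length(path) == 1) return(tibble(dg = 0, err = 0, length = 0L))
  a <- path[-length(path)]; b <- path[-1]
  w <- net$w[cbind(a, b)]
  e <- net$eps[cbind(a, b)]
  if (any(is.na(w))) {
    bad <- which(is.na(w))[1]
    abort(sprintf("No edge between %s and %s.", a[bad], b[bad]))
  }
  tibble(dg = sum(w), err = sqrt(sum(e^2)), length = length(a))
}

#' Combine path estimates into one relative free energy
#'
#' Default (`mode = "normalized"`): weights `u_i = 1 / max(e_i, err_floor)`
#' normalized to sum to one give `ddg = sum(w_i * dg_i)`, a weighted mean
#' guaranteed to lie within the range of the path values, and
#' `err = sqrt(sum(w_i^2 * e_i^2))`, the standard propagation for a
#' weighted mean of independent estimates (path correlations through shared
#' edges are knowingly ignored). `mode = "paper_literal"` instead evaluates
#' the originally printed formulas verbatim (`omega = sum(1/e)` over all
#' paths, `ddg = sum(omega * dg_i / e_i)`, `err = sqrt(sum(omega * e_i))`)
#' for auditability; these are not dimensionally a weighted mean and are
#' never the default.
#'
#' @param paths Tibble with columns `dg` and `err`, one row per simple path.
#' @param mode Combination rule, `"normalized"` or `"paper_literal"`.
#' @param err_mode Error rule, `"weighted_rss"` or `"paper_literal"`.
#' @param err_floor Errors below this floor (kcal/mol) are raised to it
#'   before weighting, keeping weights finite on noiseless networks.
#' @return A list with elements `ddg` and `err` (kcal/mol).
#' @examples
#' combine_paths(tibble::tibble(dg = c(1, 2), err = c(0.1, 0.3)))
#' @export
combine_paths <- function(paths, mode = c("normalized", "paper_literal"),
                          err_mode = c("weighted_rss", "paper_literal"),
                          err_floor = 1e-6) {
  mode <- match.arg(mode)
  err_mode <- match.arg(err_mode)
  if (nrow(paths) == 0) abort("At least one path is required.")
  if (any(paths$err < 0)) abort("Path errors must be >= 0.")
  e <- pmax(paths$err, err_floor)
  g <- paths$dg

  if (mode == "normalized") {
    u <- 1 / e
    w <- u / sum(u)
    ddg <- sum(w * g)
  } else {
    omega <- sum(1 / e)
    ddg <- sum(omega * g / e)
  }
  err <- if (err_mode == "weighted_rss") {
    u <- 1 / e
    w <- u / sum(u)
    sqrt(sum(w^2 * e^2))
  } else {
    omega <- sum(1 / e)
    sqrt(sum(omega * e))
  }
  list(ddg = ddg, err = err)
}

#' Boltzmann-combine alternative binding modes
#'
#' Exponential averaging of per-mode relative free energies:
#' `ddg = -kT * log(sum_k exp(-ddg_k / kT))`, evaluated through a
#' log-sum-exp-stable shift. The result is bounded by
#' `[min(ddg_k) - kT log N, min(ddg_k)]`. The returned error is that of the
#' dominant (minimum free energy) mode, since exponential averaging defines
#' no error rule of its own.
#'
#' @param ddg Numeric vector of per-mode relative free energies (kcal/mol).
#' @param err Numeric vector of per-mode errors (same length).
#' @param temperature Temperature in K.
#' @return A list with `ddg`, `err`, `n_modes`.
#' @examples
#' combine_binding_modes(c(-1, -1), c(0.1, 0.2)) # -1 - kT log 2
#' @export
combine_binding_modes <- function(ddg, err = rep(0, length(ddg)),
                                  temperature = 298) {
  if (length(ddg) == 0) abort("At least one binding mode is required.")
  if (length(err) != length(ddg)) abort("`err` must match `ddg` in length.")
  check_scalar_number(temperature, "temperature", positive = TRUE)
  kt <- kT(temperature)
  list(
    ddg = neg_logsumexp(ddg, kt),
    err = err[which.min(ddg)],
    n_modes = length(ddg)
  )
}

#' Per-ligand relative binding free energies versus a reference compound
#'
#' For every ligand@mode node in the reference's connected component, all
#' simple paths to the reference node are enumerated, each path's free
#' energy and error computed, and the paths combined by inverse-error
#' weighting. A ligand's alternative binding modes are then collapsed by
#' exponential averaging, and all values are shifted so the reference
#' ligand's own estimate is exactly (0, 0).
#'
#' @param net A `perturbation_network`.
#' @param reference Reference ligand identifier (its lexicographically first
#'   mode node anchors the paths) or an explicit ligand@mode node id.
#' @param temperature Temperature (K) for mode combination.
#' @param max_paths,max_length Path enumeration caps, see
#'   [enumerate_simple_paths()].
#' @param mode,err_mode,err_floor Combination rules, see [combine_paths()].
#' @return A tibble of class `fep_estimates` with columns `ligand`,
#'   `ddg_vs_ref`, `err`, `n_paths`, `modes_combined`.
#' @examples
#' edges <- tibble::tibble(node_a = c("A@a", "A@a", "B@a"),
#'                         node_b = c("B@a", "C@a", "C@a"),
#'                         mean_ddg = c(-1, -2.5, -1.5), std_err = 0)
#' relative_free_energies(build_network(edges), "A")
#' @export
relative_free_energies <- function(net, reference, temperature = 298,
                                   max_paths = 10000, max_length = NULL,
                                   mode = "normalized",
                                   err_mode = "weighted_rss",
                                   err_floor = 1e-6) {
  stopifnot(inherits(net, "perturbation_network"))
  if (length(net$nodes) == 0) abort("Empty network.")
  lignodes <- split_node(net$nodes)
  if (reference %in% net$nodes) {
    ref_node <- reference
  } else {
    cand <- sort(lignodes$node[lignodes$ligand == reference])
    if (length(cand) == 0) abort("`reference` is not in the network.")
    ref_node <- cand[1]
  }
  ref_ligand <- node_ligand(ref_node)

  comp <- connectivity_report(net)
  ref_comp <- comp$component[comp$node == ref_node]
  members <- comp$node[comp$component == ref_comp]

  per_node <- purrr::map(members, function(nd) {
    paths <- enumerate_simple_paths(net, nd, ref_node,
                                    max_paths = max_paths,
                                    max_length = max_length)
    if (length(paths) == 0) return(NULL)
    pest <- dplyr::bind_rows(purrr::map(paths, ~ path_estimate(net, .x)))
    # orient node -> reference, then negate to express node vs reference
    comb <- combine_paths(pest, mode = mode, err_mode = err_mode,
                          err_floor = err_floor)
    tibble(node = nd, ddg = -comb$ddg, err = comb$err,
           n_paths = nrow(pest))
  })
  per_node <- dplyr::bind_rows(per_node) |>
    left_join(lignodes, by = "node")

  per_ligand <- per_node |>
    group_by(.data$ligand) |>
    summarise(
      raw = list(combine_binding_modes(.data$ddg, .data$err,
                                       temperature = temperature)),
      n_paths = sum(.data$n_paths),
      modes_combined = n(),
      .groups = "drop"
    ) |>
    mutate(
      ddg_vs_ref = purrr::map_dbl(.data$raw, "ddg"),
      err = purrr::map_dbl(.data$raw, "err")
    ) |>
    select("ligand", "ddg_vs_ref", "err", "n_paths", "modes_combined")

  # anchor: the reference ligand's combined value defines zero
  ref_val <- per_ligand$ddg_vs_ref[per_ligand$ligand == ref_ligand]
  per_ligand <- per_ligand |>
    mutate(ddg_vs_ref = .data$ddg_vs_ref - ref_val)
  per_ligand$err[per_ligand$ligand == ref_ligand] <- 0
  out <- arrange(per_ligand, .data$ligand)
  class(out) <- c("fep_estimates", class(out))
  attr(out, "reference") <- ref_ligand
  out
}

#' Cycle-closure convergence report
#'
#' Computes the absolute oriented sum of edge free energies around each
#' fundamental cycle of the network (a cycle basis obtained from a spanning
#' tree; every independent cycle inconsistency appears in at least one
#' basis cycle). Closures above `threshold` are flagged: in a real study
#' such perturbations are candidates for repeat simulations.
#'
#' @param net A `perturbation_network`.
#' @param max_cycle_length Report only basis cycles with at most this many
#'   vertices (default: no limit).
#' @param threshold Flagging threshold in kcal/mol.
#' @return A tibble with columns `cycle` (list of node vectors), `length`,
#'   `closure`, `flagged`; zero rows for acyclic networks.
#' @examples
#' edges <- tibble::tibble(node_a = c("A@a", "A@a", "B@a"),
#'                         node_b = c("B@a", "C@a", "C@a"),
#'                         mean_ddg = c(1, 2.5, 1), std_err = 0.1)
#' cycle_closure_report(build_network(edges))
#' @export
cycle_closure_report <- function(net, max_cycle_length = NULL,
                                 threshold = 1.0) {
  stopifnot(inherits(net, "perturbation_network"))
  empty <- tibble(cycle = list(), length = integer(0),
                  closure = numeric(0), flagged = logical(0))
  if (nrow(net$edges) == 0) return(empty)
  if (!is.null(max_cycle_length) && max_cycle_length < 3) {
    abort("`max_cycle_length` must be >= 3.")
  }

  g <- as_igraph(net)
  mst <- igraph::mst(g)
  # non-tree edges close the fundamental cycles
  all_keys <- pair_key(net$edges$node_a, net$edges$node_b)
  mst_el <- igraph::as_edgelist(mst)
  tree_keys <- pair_key(mst_el[, 1], mst_el[, 2])
  chords <- net$edges[!all_keys %in% tree_keys, , drop = FALSE]
  if (nrow(chords) == 0) return(empty)

  rows <- purrr::pmap(chords[, c("node_a", "node_b")],
    function(node_a, node_b) {
      p <- igraph::shortest_paths(mst, from = node_a, to = node_b)$vpath[[1]]
      cyc <- igraph::as_ids(p)
      est <- path_estimate(net, cyc)
      closing <- net$w[node_b, node_a]
      tibble(cycle = list(cyc), length = length(cyc),
             closure = abs(est$dg + closing))
    })
  out <- dplyr::bind_rows(rows)
  if (!is.null(max_cycle_length)) {
    out <- filter(out, .data$length <= max_cycle_length)
  }
  out |> mutate(flagged = .data$closure > threshold) |>
    arrange(dplyr::desc(.data$closure))
}
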