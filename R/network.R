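# Aggregation of raw directional perturbation runs into a weighted
# perturbation network (adjacency of mean ddG values + symmetric error
# matrix over ligand@mode nodes).

#' Aggregate repeated directional measurements into per-edge estimates
#'
#' Backward runs are stored with the sign of the backward morph; they are
#' negated here and pooled with the forward runs. For each unordered node
#' pair the pooled mean is the edge estimate, the pooled sample standard
#' deviation divided by sqrt(n) is its standard error (0 for a single run,
#' with a warning), and the hysteresis is the absolute difference between
#' the forward mean and the negated backward mean (0 if either direction is
#' absent). Edges are reported in canonical orientation `node_a < node_b`.
#'
#' @param measurements Tibble with columns `ligand_from`, `ligand_to`,
#'   `mode_from`, `mode_to`, `direction` (forward/backward), `repeat`,
#'   `ddg` (kcal/mol).
#' @return A tibble with one row per unordered node pair: `node_a`,
#'   `node_b`, `mean_ddg` (oriented a to b), `std_err`, `n_values`,
#'   `hysteresis`.
#' @examples
#' m <- tibble::tibble(
#'   ligand_from = c("A", "B"), ligand_to = c("B", "A"),
#'   mode_from = "a", mode_to = "a",
#'   direction = c("forward", "backward"), `repeat` = 1L,
#'   ddg = c(1.0, -1.4)
#' )
#' aggregate_edges(m)
#' @export
aggregate_edges <- function(measurements) {
  if (nrow(measurements) == 0) abort("No measurements to aggregate.")
  needed <- c("ligand_from", "ligand_to", "mode_from", "mode_to",
              "direction", "ddg")
  missing <- setdiff(needed, names(measurements))
  if (length(missing) > 0) {
    abort(paste0("Missing measurement columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(measurements$direction %in% c("forward", "backward"))) {
    abort("`direction` must be 'forward' or 'backward'.")
  }
  if (any(!is.finite(measurements$ddg))) abort("Non-finite ddg values.")

  m <- measurements |>
    mutate(
      from = node_id(.data$ligand_from, .data$mode_from),
      to = node_id(.data$ligand_to, .data$mode_to)
    )
  if (any(m$from == m$to)) abort("Self-perturbations are not allowed.")
  m <- m |>
    mutate(
      node_a = pmin(.data$from, .data$to),
      node_b = pmax(.data$from, .data$to),
      # value re-expressed in the canonical a -> b orientation
      value_ab = ifelse(.data$from == .data$node_a, .data$ddg, -.data$ddg)
    )

  out <- m |>
    group_by(.data$node_a, .data$node_b) |>
    summarise(
      mean_ddg = mean(.data$value_ab),
      std_err = if (n() > 1) sd(.data$value_ab) / sqrt(n()) else 0,
      n_values = n(),
      hysteresis = {
        f <- .data$value_ab[.data$direction == "forward"]
        b <- .data$value_ab[.data$direction == "backward"]
        if (length(f) == 0 || length(b) == 0) 0 else abs(mean(f) - mean(b))
      },
      .groups = "drop"
    ) |>
    arrange(.data$node_a, .data$node_b)

  if (any(out$n_values == 1)) {
    warn(paste0(sum(out$n_values == 1),
                " edge(s) have a single run; their standard error is 0 ",
                "and downstream weighting falls back to the error floor."))
  }
  out
}

#' Aggregate measurements for a single node pair
#'
#' Convenience wrapper around [aggregate_edges()] that insists all
#' measurements refer to one unordered ligand@mode pair.
#'
#' @inheritParams aggregate_edges
#' @return A one-row edge-estimate tibble.
#' @export
aggregate_edge <- function(measurements) {
  out <- aggregate_edges(measurements)
  if (nrow(out) != 1) {
    abort("`aggregate_edge()` expects measurements for exactly one node pair.")
  }
  out
}

#' Build a perturbation network from edge estimates
#'
#' Stores the edge means in an antisymmetric weighted adjacency matrix
#' (`w[a, b] = -w[b, a]`) and the standard errors in a symmetric error
#' matrix, over the union of edge endpoints.
#'
#' @param edges Edge-estimate tibble from [aggregate_edges()] (columns
#'   `node_a`, `node_b`, `mean_ddg`, `std_err`; `n_values`/`hysteresis`
#'   carried along if present). Duplicate unordered pairs are an error:
#'   aggregate first.
#' @param charges Optional named integer vector of per-ligand net charges.
#' @return An object of class `perturbation_network` with elements `nodes`,
#'   `w`, `eps`, `edges`, `charge`.
#' @examples
#' edges <- tibble::tibble(node_a = "A@a", node_b = "B@a",
#'                         mean_ddg = 1, std_err = 0.1)
#' net <- build_network(edges)
#' net$w
#' @export
build_network <- function(edges, charges = NULL) {
  if (nrow(edges) == 0) {
    return(structure(
      list(nodes = character(0),
           w = matrix(0, 0, 0), eps = matrix(0, 0, 0),
           edges = edges, charge = charges),
      class = "perturbation_network"
    ))
  }
  key <- pair_key(edges$node_a, edges$node_b)
  if (anyDuplicated(key)) {
    abort("Duplicate node pairs in edge list; aggregate measurements first.")
  }
  if (any(edges$std_err < 0)) abort("Negative standard errors.")

  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  n <- length(nodes)
  w <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  eps <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  diag(w) <- 0; diag(eps) <- 0
  for (r in seq_len(nrow(edges))) {
    a <- edges$node_a[r]; b <- edges$node_b[r]
    w[a, b] <- edges$mean_ddg[r]; w[b, a] <- -edges$mean_ddg[r]
    eps[a, b] <- edges$std_err[r]; eps[b, a] <- edges$std_err[r]
  }

  if (is.null(charges)) {
    ligs <- unique(node_ligand(nodes))
    charges <- setNames(rep(0L, length(ligs)), ligs)
  }

  structure(
    list(nodes = nodes, w = w, eps = eps, edges = edges, charge = charges),
    class = "perturbation_network"
  )
}

#' @export
print.perturbation_network <- function(x, ...) {
  cat(sprintf("<perturbation_network: %d nodes, %d edges, %d component(s)>\n",
              length(x$nodes), nrow(x$edges),
              dplyr::n_distinct(connectivity_report(x)$component)))
  invisible(x)
}

# internal: igraph view of the network
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
}

#' Connected components of a perturbation network
#'
#' Relative free energies are only defined within a connected component.
#'
#' @param net A `perturbation_network`.
#' @return A tibble with columns `node`, `component` (integer labels).
#' @export
connectivity_report <- function(net) {
  stopifnot(inherits(net, "perturbation_network"))
  if (length(net$nodes) == 0) {
    return(tibble(node = character(0), component = integer(0)))
  }
  comp <- igraph::components(as_igraph(net))
  tibble(node = names(comp$membership),
         component = as.integer(comp$membership)) |>
    arrange(.data$node)
}

#' Categorise edges by precision
#'
#' Labels each perturbation easy, medium or difficult from the precision of
#' its estimate, together with the implied lambda-schedule recommendation
#' (fewer, same or more windows in a follow-up run).
#'
#' @param edges Edge-estimate tibble.
#' @param easy_max Standard error at or below which an edge is easy
#'   (kcal/mol).
#' @param hard_min Standard error at or above which an edge is difficult.
#' @return The edge tibble with `category` and `lambda_schedule` columns.
#' @examples
#' edges <- tibble::tibble(node_a = "A@a", node_b = "B@a",
#'                         mean_ddg = 1, std_err = 0.4)
#' categorize_edges(edges)
#' @export
categorize_edges <- function(edges, easy_max = 0.2, hard_min = 0.6) {
  if (easy_max < 0 || easy_max > hard_min) {
    abort("Thresholds must satisfy 0 <= easy_max <= hard_min.")
  }
  edges |>
    mutate(
      category = dplyr::case_when(
        .data$std_err >= hard_min ~ "difficult",
        .data$std_err <= easy_max ~ "easy",
        TRUE ~ "medium"
      ),
      lambda_schedule = dplyr::recode(.data$category,
        easy = "fewer", medium = "same", difficult = "more")
    )
}
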