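# broom-style tidiers for the package's result objects.

#' Tidy a perturbation network into its edge table
#'
#' @param x A `perturbation_network`.
#' @param ... Unused.
#' @return A tibble of edges (`node_a`, `node_b`, `mean_ddg`, `std_err`,
#'   and any carried columns).
#' @export
tidy.perturbation_network <- function(x, ...) {
  as_tibble(x$edges)
}

#' One-row summary of a perturbation network
#'
#' @param x A `perturbation_network`.
#' @param ... Unused.
#' @return A tibble with `n_nodes`, `n_ligands`, `n_edges`,
#'   `n_components`, `cycle_space_dim`, `max_std_err`.
#' @export
glance.perturbation_network <- function(x, ...) {
  comp <- connectivity_report(x)
  n_comp <- dplyr::n_distinct(comp$component)
  tibble(
    n_nodes = length(x$nodes),
    n_ligands = dplyr::n_distinct(node_ligand(x$nodes)),
    n_edges = nrow(x$edges),
    n_components = n_comp,
    cycle_space_dim = nrow(x$edges) - length(x$nodes) + n_comp,
    max_std_err = if (nrow(x$edges)) max(x$edges$std_err) else NA_real_
  )
}

#' Tidy a ground-truth object
#'
#' @param x A `fep_ground_truth`.
#' @param ... Unused.
#' @return The per-ligand tibble (`ligand`, `charge`, `true_dg`).
#' @export
tidy.fep_ground_truth <- function(x, ...) x$ligands

#' Tidy a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return A one-row tibble with the protocol, metric means and 1-sigma
#'   confidence intervals.
#' @export
tidy.metric_report <- function(x, ...) {
  tibble(
    protocol = x$protocol, n_ligands = x$n_ligands, n_boot = x$n_boot,
    r_mean = x$r_mean, r_sigma = x$r_sigma,
    mue_mean = x$mue_mean, mue_sigma = x$mue_sigma
  )
}

#' @rdname tidy.metric_report
#' @export
glance.metric_report <- function(x, ...) tidy(x)

#' Tidy a convergence verdict into per-window rows
#'
#' @param x A `convergence_verdict`.
#' @param ... Unused.
#' @return The per-window stationarity tibble.
#' @export
tidy.convergence_verdict <- function(x, ...) x$stationary_per_window

#' One-row summary of a convergence verdict
#'
#' @param x A `convergence_verdict`.
#' @param ... Unused.
#' @return A tibble with `ti_dg`, `mbar_dg`, `discrepancy`, `consistent`,
#'   `all_stationary`.
#' @export
glance.convergence_verdict <- function(x, ...) {
  tibble(
    ti_dg = x$ti_dg, mbar_dg = x$mbar_dg,
    discrepancy = x$discrepancy, consistent = x$consistent,
    all_stationary = x$all_stationary
  )
}
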