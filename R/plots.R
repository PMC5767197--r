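# ggplot2 views of the result objects.

#' Plot computed versus experimental relative free energies
#'
#' Scatter of per-ligand estimates against experimental values with 1-sigma
#' error bars and the identity line; points further from the diagonal
#' contribute more to the MUE.
#'
#' @param object A `fep_estimates` tibble.
#' @param experimental Tibble with columns `ligand`, `exp_ddg`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fep_estimates <- function(object, experimental, ...) {
  pairs <- affinity_pairs(object, experimental)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$experimental,
                                      y = .data$computed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$computed - .data$computed_err,
                                        ymax = .data$computed + .data$computed_err),
                           width = 0, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(Delta * Delta * G[exp] ~ "(kcal/mol)"),
      y = expression(Delta * Delta * G[calc] ~ "(kcal/mol)")
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_bw()
}

#' Plot a scaling-factor grid report
#'
#' R and MUE (with 1-sigma ribbons) as a function of the charge-scaling
#' factor, highlighting the MUE-minimising factor.
#'
#' @param object A `fep_scaling_grid` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fep_scaling_grid <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(
      cols = c("r_mean", "mue_mean"),
      names_to = "metric", values_to = "value"
    ) |>
    mutate(
      sigma = ifelse(.data$metric == "r_mean", object$r_sigma[
        match(.data$factor, object$factor)], object$mue_sigma[
        match(.data$factor, object$factor)]),
      metric = dplyr::recode(.data$metric, r_mean = "Pearson R",
                             mue_mean = "MUE (kcal/mol)")
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$factor, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sigma,
                                      ymax = .data$value + .data$sigma),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = object$factor[object$best_mue][1],
      linetype = "dotted"
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "charge scaling factor", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot cycle-closure diagnostics
#'
#' Closure magnitude per fundamental cycle, coloured by whether the cycle
#' exceeds the convergence threshold.
#'
#' @param closures Tibble from [cycle_closure_report()].
#' @param threshold Threshold line to draw, kcal/mol.
#' @return A ggplot object.
#' @export
plot_cycle_closure <- function(closures, threshold = 1.0) {
  df <- closures |>
    mutate(label = purrr::map_chr(.data$cycle, ~ paste(.x, collapse = ">")))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, .data$closure),
    y = .data$closure, fill = .data$flagged
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "cycle closure (kcal/mol)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw()
}
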