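# End-to-end orchestration: measurements -> network -> diagnostics ->
# per-ligand estimates (with and without charge-scaling corrections, full
# and same-charge subsets) -> metric reports, written to a run directory.

#' Analysis run configuration
#'
#' Collects every tunable of the pipeline in one serialisable list. All
#' thresholds are in kcal/mol unless noted.
#'
#' @param seed Seed for synthetic generation and bootstraps.
#' @param temperature Temperature (K) for mode combination and IC50
#'   conversion.
#' @param reference Reference ligand id (NULL: the study's own reference).
#' @param max_paths,max_length Simple-path enumeration caps.
#' @param err_floor Path-error floor before inverse-error weighting.
#' @param combine_mode,combine_err_mode Path combination rules, see
#'   [combine_paths()].
#' @param n_boot_parametric,n_boot_dataset Bootstrap replicate counts.
#' @param cycle_threshold Cycle-closure flag threshold.
#' @param hysteresis_tol Forward/backward agreement tolerance.
#' @param easy_max,hard_min Edge precision categorisation cutoffs.
#' @param consistency_tol TI-MBAR agreement tolerance.
#' @param adf_alpha Significance level of the stationarity test.
#' @param discard_fraction Equilibration fraction discarded per window.
#' @param exp_sigma Assumed experimental uncertainty for ceiling R.
#' @param charge_rule A [charge_rule()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, temperature = 298, reference = NULL,
                       max_paths = 10000, max_length = NULL,
                       err_floor = 1e-6,
                       combine_mode = "normalized",
                       combine_err_mode = "weighted_rss",
                       n_boot_parametric = 10000, n_boot_dataset = 1000,
                       cycle_threshold = 1.0, hysteresis_tol = 0.5,
                       easy_max = 0.2, hard_min = 0.6,
                       consistency_tol = 0.5, adf_alpha = 0.05,
                       discard_fraction = 0.05, exp_sigma = 0.4,
                       charge_rule = fepnet::charge_rule()) {
  cfg <- as.list(environment())
  for (nm in c("cycle_threshold", "hysteresis_tol", "consistency_tol")) {
    check_scalar_number(cfg[[nm]], nm, positive = TRUE)
  }
  structure(cfg, class = "run_config")
}

#' The largest subset of ligands sharing one net charge
#'
#' Ties between charge classes of equal size are broken towards the class
#' containing the lexicographically smallest ligand id, so the selection is
#' deterministic.
#'
#' @param charges Named integer vector of per-ligand net charges.
#' @return Character vector of ligand ids.
#' @export
same_charge_subset <- function(charges) {
  if (length(charges) == 0) return(character(0))
  classes <- split(names(charges), charges)
  sizes <- lengths(classes)
  firsts <- vapply(classes, function(x) min(x), character(1))
  best <- order(-sizes, firsts)[1]
  sort(classes[[best]])
}

#' The four analysis protocol variants
#'
#' Runs the path-combination analysis four ways: on the full network
#' (`full`), restricted to the largest same-net-charge ligand subset
#' (`same_charge`), and both again with charge-scaling corrections applied
#' to the edges (`full_scaled`, `same_charge_scaled`). Scaled variants are
#' skipped when no scaling table is supplied.
#'
#' @param edges Edge-estimate tibble.
#' @param charges Named integer vector of per-ligand net charges.
#' @param reference Reference ligand id.
#' @param scaling_table Optional scaling table for the corrected variants.
#' @param config A [run_config()].
#' @return Named list of `fep_estimates` tibbles.
#' @export
protocol_variants <- function(edges, charges, reference,
                              scaling_table = NULL, config = run_config()) {
  run_one <- function(edge_tbl) {
    net <- build_network(edge_tbl, charges = charges)
    relative_free_energies(
      net, reference,
      temperature = config$temperature,
      max_paths = config$max_paths, max_length = config$max_length,
      mode = config$combine_mode, err_mode = config$combine_err_mode,
      err_floor = config$err_floor
    )
  }
  subset_edges <- function(edge_tbl, keep) {
    filter(edge_tbl, node_ligand(.data$node_a) %in% keep &
             node_ligand(.data$node_b) %in% keep)
  }

  keep <- same_charge_subset(charges)
  # if the reference itself falls outside the same-charge subset, anchor the
  # restricted runs on the subset's lexicographically first ligand instead
  same_ref <- if (reference %in% keep) reference else keep[1]
  run_same <- function(edge_tbl) {
    sub <- subset_edges(edge_tbl, keep)
    present <- unique(node_ligand(c(sub$node_a, sub$node_b)))
    if (nrow(sub) == 0 || !same_ref %in% present) return(NULL)
    net <- build_network(sub, charges = charges)
    relative_free_energies(
      net, same_ref,
      temperature = config$temperature,
      max_paths = config$max_paths, max_length = config$max_length,
      mode = config$combine_mode, err_mode = config$combine_err_mode,
      err_floor = config$err_floor
    )
  }

  out <- list(full = run_one(edges))
  out$same_charge <- run_same(edges)
  if (!is.null(scaling_table)) {
    corrected <- apply_corrections(edges, scaling_table, charges,
                                   rule = config$charge_rule)
    out$full_scaled <- run_one(corrected)
    out$same_charge_scaled <- run_same(corrected)
  }
  purrr::compact(out)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Generates a ground-truth study, simulates measurements, gradients, an
#' IC50 assay and a scaling table, then runs aggregation, network building,
#' convergence diagnostics, cycle closure, protocol variants and metric
#' reports, writing every table to `out_dir` together with a manifest.
#' Input tables can instead be supplied directly through `inputs` (a list
#' with elements `measurements`, `ic50`, and optionally `scaling_table`,
#' `charges`, `reference`, `gradients`), in which case no synthesis is
#' performed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param study Parameters of the synthetic study: a list with `n_ligands`,
#'   `dg_span`, `charged_fraction`, `max_modes`, `extra_chords`, and a
#'   [noise_model()] under `noise`. Ignored when `inputs` is given.
#' @param inputs Optional pre-built input tables (see Details).
#' @return Invisibly, a list with every intermediate object (`truth`,
#'   `measurements`, `edges`, `network`, `closures`, `convergence`,
#'   `estimates`, `metrics`, `files`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("fepnet-"),
                         study = list(n_ligands = 10, dg_span = 5,
                                      charged_fraction = 0.2, max_modes = 2,
                                      extra_chords = 3,
                                      noise = noise_model(edge_sigma = 0.3,
                                                          n_repeats = 3)),
                         inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(writer, obj, name) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    files[[name]] <<- p
  }

  truth <- NULL
  if (is.null(inputs)) {
    noise <- study$noise %||% noise_model(seed = config$seed)
    noise$seed <- config$seed
    truth <- generate_ground_truth(
      n_ligands = study$n_ligands %||% 10,
      dg_span = study$dg_span %||% 5,
      charged_fraction = study$charged_fraction %||% 0,
      max_modes = study$max_modes %||% 1,
      seed = config$seed, temperature = config$temperature
    )
    topo <- generate_topology(truth, extra_chords = study$extra_chords %||% 3,
                              seed = config$seed)
    measurements <- simulate_edges(truth, topo, noise)
    ic50 <- simulate_experiment(truth, noise, temperature = config$temperature)
    scaling_table <- simulate_scaling_table(truth, seed = config$seed)
    charges <- setNames(truth$ligands$charge, truth$ligands$ligand)
    reference <- config$reference %||% truth$reference
    gradients <- simulate_gradients(
      target_dg = measurements$ddg[1], seed = config$seed
    )
    emit(write_ground_truth_json, truth, "ground_truth.json")
  } else {
    measurements <- inputs$measurements
    ic50 <- inputs$ic50
    scaling_table <- inputs$scaling_table
    charges <- inputs$charges
    reference <- config$reference %||% inputs$reference
    gradients <- inputs$gradients
    if (is.null(measurements) || is.null(ic50) || is.null(reference)) {
      abort("`inputs` needs at least measurements, ic50 and reference.")
    }
    if (is.null(charges)) {
      ligs <- unique(c(measurements$ligand_from, measurements$ligand_to))
      charges <- setNames(rep(0L, length(ligs)), ligs)
    }
  }
  emit(write_measurements, measurements, "measurements.csv")
  emit(write_ic50, ic50, "ic50.csv")
  if (!is.null(scaling_table)) {
    emit(write_scaling_table, scaling_table, "scaling_table.csv")
  }

  edges <- aggregate_edges(measurements)
  edges <- categorize_edges(edges, easy_max = config$easy_max,
                            hard_min = config$hard_min)
  emit(readr::write_csv, edges, "edges.csv")

  net <- build_network(select(edges, "node_a", "node_b", "mean_ddg",
                              "std_err", "n_values", "hysteresis"),
                       charges = charges)
  emit(write_network_json, net, "network.json")

  closures <- cycle_closure_report(net, threshold = config$cycle_threshold)
  closure_tbl <- closures |>
    mutate(cycle = purrr::map_chr(.data$cycle, paste, collapse = ">"))
  emit(readr::write_csv, closure_tbl, "cycle_closure.csv")

  convergence <- NULL
  if (!is.null(gradients)) {
    convergence <- convergence_report(
      gradients, discard_fraction = config$discard_fraction,
      alpha = config$adf_alpha, tol = config$consistency_tol
    )
    p <- file.path(out_dir, "convergence.json")
    jsonlite::write_json(
      list(ti_dg = convergence$ti_dg,
           all_stationary = convergence$all_stationary,
           stationary_per_window = convergence$stationary_per_window),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    files[["convergence.json"]] <- p
  }

  estimates <- protocol_variants(
    select(edges, "node_a", "node_b", "mean_ddg", "std_err",
           "n_values", "hysteresis"),
    charges, reference, scaling_table = scaling_table, config = config
  )
  for (nm in names(estimates)) {
    emit(write_estimates, estimates[[nm]],
         paste0("estimates_", nm, ".csv"))
  }

  exp_ddg <- experimental_ddg(ic50, reference,
                              temperature = config$temperature)
  metrics <- purrr::imap(estimates, function(est, nm) {
    pairs <- affinity_pairs(est, exp_ddg)
    list(
      parametric = bootstrap_parametric(pairs,
                                        n_boot = config$n_boot_parametric,
                                        seed = config$seed),
      dataset = bootstrap_dataset(pairs, n_boot = config$n_boot_dataset,
                                  seed = config$seed)
    )
  })
  metric_tbl <- purrr::imap(metrics, function(m, nm) {
    dplyr::bind_rows(tidy(m$parametric), tidy(m$dataset)) |>
      mutate(protocol_variant = nm, .before = 1)
  }) |> dplyr::bind_rows()
  emit(readr::write_csv, metric_tbl, "metrics.csv")

  ceiling <- ceiling_r(exp_ddg$exp_ddg, exp_sigma = config$exp_sigma,
                       n_boot = config$n_boot_parametric, seed = config$seed)

  manifest <- list(
    package = "fepnet",
    version = as.character(utils::packageVersion("fepnet")),
    seed = config$seed,
    temperature = config$temperature,
    reference = reference,
    ceiling_r = ceiling,
    config_hash = rlang::hash(config[setdiff(names(config), "charge_rule")]),
    files = names(files)
  )
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files[["manifest.json"]] <- p

  invisible(list(
    truth = truth, measurements = measurements, edges = edges,
    network = net, closures = closures, convergence = convergence,
    estimates = estimates, metrics = metrics, ceiling_r = ceiling,
    experimental = exp_ddg, files = files, out_dir = out_dir
  ))
}
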