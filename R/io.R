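# Readers and writers for the plain-text interchange schemas: measurement
# CSV, gradient CSV, IC50 CSV, scaling-table CSV, edge/estimate CSVs, and
# JSON serialisation of networks and reports.

measurement_cols <- c("ligand_from", "ligand_to", "mode_from", "mode_to",
                      "direction", "repeat", "ddg")

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read / write perturbation measurement CSVs
#'
#' Columns: `ligand_from`, `ligand_to`, `mode_from`, `mode_to`, `direction`
#' (forward/backward), `repeat`, `ddg` (kcal/mol; backward runs carry
#' the sign of the backward morph).
#'
#' @param path File path.
#' @param measurements Measurement tibble.
#' @return `read_measurements()` returns the tibble;
#'   `write_measurements()` returns `path` invisibly.
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, measurement_cols, "Measurement file")
  df
}

#' @rdname read_measurements
#' @export
write_measurements <- function(measurements, path) {
  check_columns(measurements, measurement_cols, "Measurement tibble")
  readr::write_csv(measurements, path)
  invisible(path)
}

#' Read / write lambda-gradient CSVs
#'
#' Columns: `lambda`, `sample_index`, `dudl` (kcal/mol).
#'
#' @param path File path.
#' @param gradients Gradient tibble.
#' @return The tibble, or `path` invisibly for the writer.
#' @export
read_gradients <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("lambda", "sample_index", "dudl"), "Gradient file")
  df
}

#' @rdname read_gradients
#' @export
write_gradients <- function(gradients, path) {
  check_columns(gradients, c("lambda", "sample_index", "dudl"),
                "Gradient tibble")
  readr::write_csv(gradients, path)
  invisible(path)
}

#' Read / write IC50 CSVs
#'
#' Columns: `ligand`, `ic50`.
#'
#' @param path File path.
#' @param ic50 IC50 tibble.
#' @return The tibble, or `path` invisibly for the writer.
#' @export
read_ic50 <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("ligand", "ic50"), "IC50 file")
  if (any(df$ic50 <= 0)) abort("IC50 values must be positive.")
  df
}

#' @rdname read_ic50
#' @export
write_ic50 <- function(ic50, path) {
  check_columns(ic50, c("ligand", "ic50"), "IC50 tibble")
  readr::write_csv(ic50, path)
  invisible(path)
}

#' Read / write charge-scaling tables
#'
#' Columns: `ligand`, `environment` (free/bound), `factor`, `dg_scaled`
#' (kcal/mol).
#'
#' @param path File path.
#' @param table Scaling-table tibble.
#' @return The tibble, or `path` invisibly for the writer.
#' @export
read_scaling_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("ligand", "environment", "factor", "dg_scaled"),
                "Scaling table")
  if (!all(df$environment %in% c("free", "bound"))) {
    abort("`environment` must be 'free' or 'bound'.")
  }
  df
}

#' @rdname read_scaling_table
#' @export
write_scaling_table <- function(table, path) {
  check_columns(table, c("ligand", "environment", "factor", "dg_scaled"),
                "Scaling table")
  readr::write_csv(table, path)
  invisible(path)
}

#' Read / write per-ligand estimate CSVs
#'
#' Columns: `ligand`, `ddg_vs_ref`, `err`, `n_paths`, `modes_combined`.
#'
#' @param path File path.
#' @param estimates `fep_estimates` tibble.
#' @return The tibble, or `path` invisibly for the writer.
#' @export
read_estimates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("ligand", "ddg_vs_ref", "err"), "Estimate file")
  class(df) <- c("fep_estimates", class(df))
  df
}

#' @rdname read_estimates
#' @export
write_estimates <- function(estimates, path) {
  check_columns(estimates, c("ligand", "ddg_vs_ref", "err"),
                "Estimate tibble")
  readr::write_csv(estimates, path)
  invisible(path)
}

#' Serialise a perturbation network to JSON
#'
#' @param net A `perturbation_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "perturbation_network"))
  jsonlite::write_json(
    list(
      nodes = net$nodes,
      edges = net$edges,
      charge = as.list(net$charge)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Rebuild a perturbation network from its JSON serialisation
#'
#' @param path JSON file written by [write_network_json()].
#' @return A `perturbation_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  charges <- unlist(obj$charge)
  build_network(as_tibble(obj$edges), charges = charges)
}

#' Ground-truth JSON sidecar
#'
#' Writes the unobserved quantities of a synthetic study (per-ligand true
#' free energies, charges, per-node mode free energies, reference) so test
#' assertions can compare estimates against truth.
#'
#' @param truth A `fep_ground_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "fep_ground_truth"))
  jsonlite::write_json(
    list(ligands = truth$ligands, nodes = truth$nodes,
         reference = truth$reference, temperature = truth$temperature),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(ligands = as_tibble(obj$ligands), nodes = as_tibble(obj$nodes),
         reference = obj$reference, temperature = obj$temperature),
    class = "fep_ground_truth"
  )
}
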