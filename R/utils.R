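# Boltzmann constant in kcal/(mol K)
.kB <- 0.0019872041

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return kT in kcal/mol.
#' @examples
#' kT(298) # ~0.592
#' @export
kT <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB * temperature
}

# ligand@mode composite node identifiers
node_id <- function(ligand, mode) paste0(ligand, "@", mode)

split_node <- function(node) {
  parts <- strsplit(node, "@", fixed = TRUE)
  tibble(
    node = node,
    ligand = vapply(parts, `[`, character(1), 1L),
    mode = vapply(parts, `[`, character(1), 2L)
  )
}

node_ligand <- function(node) sub("@.*$", "", node)

# canonical unordered pair key, independent of orientation
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# numerically stable -kT * log(sum(exp(-g/kT)))
neg_logsumexp <- function(g, kt) {
  m <- min(g)
  m - kt * log(sum(exp(-(g - m) / kt)))
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
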