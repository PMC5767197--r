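# Synthetic perturbation studies with known ground truth.
#
# The generator emulates the statistical structure of an alchemical relative
# binding free energy study: per-ligand true binding free energies, a
# connected ligand@mode perturbation topology rich in simple cycles,
# directional Gaussian edge noise with hysteresis and repeats, alternative
# binding modes, net-charge labels with a systematic error on charge-changing
# edges, AR(1) lambda-gradient timeseries, IC50 measurements, and
# charge-scaling free energy tables. No molecular structures or trajectories
# are modelled: the generator produces estimates, not configurations.

#' Noise model for a synthetic perturbation study
#'
#' Bundles the stochastic parameters of the edge and experiment simulators.
#'
#' @param edge_sigma Gaussian noise on each individual run, kcal/mol.
#' @param hysteresis_sigma Extra direction-specific spread (forward vs
#'   backward disagreement), kcal/mol. Modelled as independent noise per
#'   direction, not a fixed offset.
#' @param n_repeats Independent repeats per direction (>= 1).
#' @param charge_change_bias Systematic offset (kcal/mol) applied to edges
#'   whose endpoint ligands differ in net charge, oriented towards the
#'   charged endpoint. Emulates the overestimation of relative binding free
#'   energies observed for charge-changing perturbations.
#' @param exp_sigma Experimental (assay) noise in kcal/mol; the default of
#'   0.4 kcal/mol is the customary estimate of IC50 assay uncertainty.
#' @param seed Integer seed making every simulator deterministic.
#' @return A list of class `fep_noise_model`.
#' @examples
#' noise_model(edge_sigma = 0.3, n_repeats = 3, seed = 1)
#' @export
noise_model <- function(edge_sigma = 0.2, hysteresis_sigma = 0,
                        n_repeats = 1, charge_change_bias = 0,
                        exp_sigma = 0.4, seed = 1) {
  stopifnot(edge_sigma >= 0, hysteresis_sigma >= 0, exp_sigma >= 0)
  if (n_repeats < 1) abort("`n_repeats` must be >= 1.")
  structure(
    list(
      edge_sigma = edge_sigma, hysteresis_sigma = hysteresis_sigma,
      n_repeats = as.integer(n_repeats),
      charge_change_bias = charge_change_bias,
      exp_sigma = exp_sigma, seed = as.integer(seed)
    ),
    class = "fep_noise_model"
  )
}

#' Generate a ground-truth ligand series
#'
#' Draws per-ligand binding free energies spanning at most `dg_span`
#' kcal/mol, assigns net charges (-1 to a rounded-up fraction of the series,
#' 0 to the rest), and gives each ligand between 1 and `max_modes` binding
#' modes. Per-mode node free energies are constructed so that Boltzmann
#' (exponential) averaging over a ligand's modes at `temperature` recovers
#' the ligand's true binding free energy exactly; mode offsets therefore
#' carry no net free energy, only a redistribution across poses.
#'
#' @param n_ligands Number of ligands (>= 3).
#' @param dg_span Maximum spread of true binding free energies, kcal/mol.
#' @param charged_fraction Fraction of ligands carrying net charge -1;
#'   `ceiling(charged_fraction * n_ligands)` ligands are charged.
#' @param max_modes Maximum number of binding modes per ligand; mode counts
#'   are uniform on `1:max_modes`.
#' @param seed Integer seed.
#' @param temperature Temperature (K) at which the mode decomposition is
#'   Boltzmann-consistent.
#' @return A list of class `fep_ground_truth` with elements `ligands`
#'   (tibble: ligand, charge, true_dg), `nodes` (tibble: ligand, mode, node,
#'   dg_node), `reference` (ligand id) and `temperature`.
#' @examples
#' truth <- generate_ground_truth(5, dg_span = 3, seed = 1)
#' truth$ligands
#' @export
generate_ground_truth <- function(n_ligands, dg_span = 5,
                                  charged_fraction = 0, max_modes = 1,
                                  seed = 1, temperature = 298) {
  if (!is.numeric(n_ligands) || n_ligands < 3) {
    abort("`n_ligands` must be >= 3.")
  }
  check_scalar_number(dg_span, "dg_span", positive = TRUE)
  if (charged_fraction < 0 || charged_fraction > 1) {
    abort("`charged_fraction` must lie in [0, 1].")
  }
  if (max_modes < 1) abort("`max_modes` must be >= 1.")
  n_ligands <- as.integer(n_ligands)

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ids <- sprintf("L%02d", seq_len(n_ligands))
  true_dg <- runif(n_ligands, min = -dg_span / 2, max = dg_span / 2)
  true_dg <- true_dg - mean(true_dg)
  # renormalise so the realised span never exceeds dg_span
  spread <- diff(range(true_dg))
  if (spread > dg_span) true_dg <- true_dg * (dg_span / spread)

  n_charged <- ceiling(charged_fraction * n_ligands)
  charge <- rep(0L, n_ligands)
  if (n_charged > 0) {
    charge[sample.int(n_ligands, n_charged)] <- -1L
  }

  n_modes <- if (max_modes == 1) rep(1L, n_ligands) else {
    sample.int(max_modes, n_ligands, replace = TRUE)
  }

  kt <- kT(temperature)
  nodes <- purrr::map(seq_len(n_ligands), function(i) {
    k <- n_modes[i]
    labels <- letters[seq_len(k)]
    # raw offsets: dominant mode at 0, alternatives less favourable
    delta <- c(0, sort(runif(k - 1, 0.2, 2.5)))
    # shift so exponential averaging over modes returns true_dg exactly
    shift <- neg_logsumexp(delta, kt)
    tibble(
      ligand = ids[i], mode = labels,
      node = node_id(ids[i], labels),
      dg_node = true_dg[i] + delta - shift
    )
  })
  nodes <- dplyr::bind_rows(nodes)

  structure(
    list(
      ligands = tibble(ligand = ids, charge = charge, true_dg = true_dg),
      nodes = nodes,
      reference = ids[1],
      temperature = temperature
    ),
    class = "fep_ground_truth"
  )
}

# save/restore global RNG state so generators are pure for a given seed
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a connected perturbation topology
#'
#' Builds an undirected edge set over all ligand@mode nodes: a uniformly
#' random spanning tree (via a random Pruefer sequence) guarantees
#' connectivity, and `extra_chords` additional edges sampled uniformly from
#' the absent pairs give the network a controllable number of independent
#' simple cycles (cycle-space dimension = `extra_chords`).
#'
#' @param truth A `fep_ground_truth` object.
#' @param extra_chords Number of chord edges beyond the spanning tree.
#' @param seed Integer seed.
#' @return A tibble with columns `node_a`, `node_b` (one row per undirected
#'   edge, no duplicates, no self-edges).
#' @examples
#' truth <- generate_ground_truth(5, seed = 1)
#' generate_topology(truth, extra_chords = 2, seed = 1)
#' @export
generate_topology <- function(truth, extra_chords = 0, seed = 1) {
  stopifnot(inherits(truth, "fep_ground_truth"))
  if (extra_chords < 0) abort("`extra_chords` must be >= 0.")
  nodes <- truth$nodes$node
  n <- length(nodes)
  if (n < 2) abort("Topology needs at least two nodes.")

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  if (n == 2) {
    tree <- matrix(c(1L, 2L), ncol = 2)
  } else {
    # random Pruefer sequence -> uniform random labelled spanning tree
    pruefer <- sample.int(n, n - 2, replace = TRUE)
    degree <- rep(1L, n)
    for (p in pruefer) degree[p] <- degree[p] + 1L
    tree <- matrix(0L, nrow = n - 1, ncol = 2)
    ptr <- 1L
    for (p in pruefer) {
      leaf <- which(degree == 1L)[1]
      tree[ptr, ] <- c(leaf, p)
      ptr <- ptr + 1L
      degree[leaf] <- degree[leaf] - 1L
      degree[p] <- degree[p] - 1L
    }
    last <- which(degree == 1L)
    tree[ptr, ] <- last[1:2]
  }

  key <- function(i, j) pair_key(as.character(i), as.character(j))
  used <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(tree))) {
    assign(key(tree[r, 1], tree[r, 2]), TRUE, envir = used)
  }

  max_chords <- n * (n - 1) / 2 - (n - 1)
  n_chords <- min(extra_chords, max_chords)
  chords <- matrix(0L, nrow = n_chords, ncol = 2)
  if (n_chords > 0) {
    all_pairs <- utils::combn(n, 2)
    free <- which(!vapply(
      seq_len(ncol(all_pairs)),
      function(c) exists(key(all_pairs[1, c], all_pairs[2, c]), envir = used),
      logical(1)
    ))
    pick <- free[sample.int(length(free), n_chords)]
    chords <- t(all_pairs[, pick, drop = FALSE])
  }

  edges <- rbind(tree, chords)
  tibble(
    node_a = nodes[pmin(edges[, 1], edges[, 2])],
    node_b = nodes[pmax(edges[, 1], edges[, 2])]
  ) |> dplyr::arrange(.data$node_a, .data$node_b)
}

#' Simulate directional perturbation measurements on a topology
#'
#' For every edge and repeat, one forward (a to b) and one backward (b to a)
#' run is drawn. The forward value is the true node free energy difference
#' plus independent Gaussian noise, direction-specific hysteresis noise, and
#' a systematic charge-change offset; the backward value is stored with the
#' sign of the backward morph and is only negated at aggregation time,
#' matching the file provenance of real runs.
#'
#' @param truth A `fep_ground_truth` object.
#' @param topology Edge tibble from [generate_topology()].
#' @param noise A [noise_model()].
#' @param ligand_bias Optional named numeric vector of per-ligand systematic
#'   offsets (kcal/mol) added to each ligand's computed free energy, used to
#'   emulate force-field polarisation errors that the charge-scaling
#'   correction targets (see [scaling_ligand_bias()]).
#' @return A tibble of measurements with columns `ligand_from`, `ligand_to`,
#'   `mode_from`, `mode_to`, `direction`, `repeat`, `ddg`.
#' @examples
#' truth <- generate_ground_truth(5, seed = 1)
#' topo <- generate_topology(truth, seed = 1)
#' simulate_edges(truth, topo, noise_model(edge_sigma = 0.2, seed = 2))
#' @export
simulate_edges <- function(truth, topology, noise = noise_model(),
                           ligand_bias = NULL) {
  stopifnot(inherits(truth, "fep_ground_truth"),
            inherits(noise, "fep_noise_model"))
  if (!all(c(topology$node_a, topology$node_b) %in% truth$nodes$node)) {
    abort("Topology refers to nodes absent from the ground truth.")
  }

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(noise$seed)

  dg <- setNames(truth$nodes$dg_node, truth$nodes$node)
  q <- setNames(truth$ligands$charge, truth$ligands$ligand)
  bias <- setNames(rep(0, nrow(truth$ligands)), truth$ligands$ligand)
  if (!is.null(ligand_bias)) bias[names(ligand_bias)] <- ligand_bias

  rows <- purrr::pmap(topology, function(node_a, node_b) {
    la <- node_ligand(node_a); lb <- node_ligand(node_b)
    true_fwd <- (dg[[node_b]] + bias[[lb]]) - (dg[[node_a]] + bias[[la]])
    # systematic error oriented towards the charged endpoint
    qs <- sign(abs(q[[lb]]) - abs(q[[la]]))
    sys_fwd <- true_fwd + qs * noise$charge_change_bias
    nr <- noise$n_repeats
    fwd <- sys_fwd + rnorm(nr, 0, noise$edge_sigma) +
      rnorm(nr, 0, noise$hysteresis_sigma)
    bwd <- -sys_fwd + rnorm(nr, 0, noise$edge_sigma) +
      rnorm(nr, 0, noise$hysteresis_sigma)
    pa <- split_node(node_a); pb <- split_node(node_b)
    tibble(
      ligand_from = c(rep(pa$ligand, nr), rep(pb$ligand, nr)),
      ligand_to = c(rep(pb$ligand, nr), rep(pa$ligand, nr)),
      mode_from = c(rep(pa$mode, nr), rep(pb$mode, nr)),
      mode_to = c(rep(pb$mode, nr), rep(pa$mode, nr)),
      direction = rep(c("forward", "backward"), each = nr),
      `repeat` = rep(seq_len(nr), 2),
      ddg = c(fwd, bwd)
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate lambda-gradient timeseries for one perturbation
#'
#' The mean gradient curve is a fixed quadratic polynomial rescaled so that
#' its trapezoidal integral over the lambda grid equals `target_dg`; each
#' window's samples add stationary AR(1) noise, and a non-zero `drift` adds
#' a linear-in-time trend (total `drift` kcal/mol over the trajectory) that
#' renders the series non-stationary.
#'
#' @param target_dg Free energy (kcal/mol) the thermodynamic integration of
#'   the noiseless series must return.
#' @param n_lambda Number of evenly spaced lambda windows on \[0, 1\].
#' @param n_samples Samples per window.
#' @param ar1_rho AR(1) autocorrelation of the noise, in \[0, 1).
#' @param drift Linear trend over the whole trajectory, kcal/mol.
#' @param noise_sigma Marginal standard deviation of the AR(1) noise,
#'   kcal/mol.
#' @param seed Integer seed.
#' @return A tibble with columns `lambda`, `sample_index`, `dudl`.
#' @examples
#' g <- simulate_gradients(2.0, n_lambda = 5, n_samples = 50, seed = 1)
#' ti_estimate(g)
#' @export
simulate_gradients <- function(target_dg, n_lambda = 11, n_samples = 200,
                               ar1_rho = 0, drift = 0, noise_sigma = 1,
                               seed = 1) {
  if (n_lambda < 2) abort("`n_lambda` must be >= 2.")
  if (ar1_rho < 0 || ar1_rho >= 1) abort("`ar1_rho` must lie in [0, 1).")
  stopifnot(noise_sigma >= 0, n_samples >= 1)

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  lam <- seq(0, 1, length.out = n_lambda)
  base <- 1 + lam - lam^2            # fixed smooth quadratic shape
  trap <- sum(diff(lam) * (head(base, -1) + base[-1]) / 2)
  mean_curve <- base * (target_dg / trap)

  purrr::map2(lam, mean_curve, function(l, mu) {
    eps <- numeric(n_samples)
    if (noise_sigma > 0) {
      innov_sd <- noise_sigma * sqrt(1 - ar1_rho^2)
      eps[1] <- rnorm(1, 0, noise_sigma)
      if (n_samples > 1) {
        z <- rnorm(n_samples - 1, 0, innov_sd)
        for (t in 2:n_samples) eps[t] <- ar1_rho * eps[t - 1] + z[t - 1]
      }
    }
    trend <- drift * (seq_len(n_samples) - 1) / max(n_samples - 1, 1)
    tibble(lambda = l, sample_index = seq_len(n_samples),
           dudl = mu + eps + trend)
  }) |> dplyr::bind_rows()
}

#' Simulate an IC50 assay consistent with the ground truth
#'
#' Inverts the IC50-to-free-energy relation: taking the reference ligand's
#' IC50 as 1 (arbitrary units; only ratios matter), each ligand gets
#' `IC50(L) = exp((dG_L - dG_ref + eps) / kT)` with Gaussian assay noise
#' `eps ~ N(0, exp_sigma)`.
#'
#' @param truth A `fep_ground_truth` object.
#' @param noise A [noise_model()]; only `exp_sigma` and `seed` are used.
#' @param temperature Assay temperature, K.
#' @return A tibble with columns `ligand`, `ic50` (all positive).
#' @examples
#' truth <- generate_ground_truth(5, seed = 1)
#' simulate_experiment(truth, noise_model(exp_sigma = 0, seed = 1))
#' @export
simulate_experiment <- function(truth, noise = noise_model(),
                                temperature = 298) {
  stopifnot(inherits(truth, "fep_ground_truth"),
            inherits(noise, "fep_noise_model"))
  check_scalar_number(temperature, "temperature", positive = TRUE)

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(noise$seed + 1L) # decouple from the edge noise stream

  lig <- truth$ligands
  ref_dg <- lig$true_dg[lig$ligand == truth$reference]
  eps <- rnorm(nrow(lig), 0, noise$exp_sigma)
  eps[lig$ligand == truth$reference] <- 0
  tibble(
    ligand = lig$ligand,
    ic50 = exp((lig$true_dg - ref_dg + eps) / kT(temperature))
  )
}

#' Simulate a charge-scaling free energy table
#'
#' Emulates the inputs of the charge-scaling correction: the free energy of
#' scaling a ligand's partial charges by `factor` in the free (water) and
#' bound (protein) environments. Entries are zero at factor 1, grow linearly
#' in (1 - factor), are larger in the bound leg than the free leg, and are
#' larger in magnitude for charged ligands.
#'
#' @param truth A `fep_ground_truth` object.
#' @param factors Scaling factors in (0, 1], e.g. `seq(1, 0.5, by = -0.1)`.
#' @param polarisation_strength Scale (kcal/mol) of the per-ligand
#'   polarisation susceptibility; 0 gives an all-zero table.
#' @param seed Integer seed.
#' @return A tibble of class `fep_scaling_table` with columns `ligand`,
#'   `environment` (free/bound), `factor`, `dg_scaled`.
#' @examples
#' truth <- generate_ground_truth(4, seed = 1)
#' simulate_scaling_table(truth, c(1, 0.7, 0.5), 1, seed = 1)
#' @export
simulate_scaling_table <- function(truth, factors = seq(1, 0.5, by = -0.1),
                                   polarisation_strength = 1, seed = 1) {
  stopifnot(inherits(truth, "fep_ground_truth"))
  if (length(factors) == 0) abort("`factors` must be non-empty.")
  if (any(factors <= 0 | factors > 1)) abort("`factors` must lie in (0, 1].")
  stopifnot(polarisation_strength >= 0)

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  lig <- truth$ligands
  # susceptibility: charged ligands polarise roughly twice as strongly
  suscept <- abs(rnorm(nrow(lig), 0, 1)) * polarisation_strength *
    (1 + abs(lig$charge))
  grid <- tidyr::expand_grid(
    ligand = lig$ligand,
    environment = c("free", "bound"),
    factor = sort(unique(factors), decreasing = TRUE)
  )
  s <- setNames(suscept, lig$ligand)
  env_gain <- c(free = 0.4, bound = 1.0)
  out <- grid |>
    mutate(dg_scaled = unname(s[.data$ligand]) *
             unname(env_gain[.data$environment]) * (1 - .data$factor))
  class(out) <- c("fep_scaling_table", class(out))
  out
}

#' Per-ligand polarisation bias implied by a scaling table
#'
#' Returns, for each ligand, minus the bound-minus-free scaling free energy
#' difference at `factor`. Adding this vector as `ligand_bias` in
#' [simulate_edges()] produces a study whose systematic per-ligand errors
#' are exactly cancelled by the charge-scaling correction at that factor,
#' which is how a "polarisation mechanism at factor f" study is generated
#' for self-consistency checks.
#'
#' @param table A scaling table (see [simulate_scaling_table()]).
#' @param factor The scaling factor of the generating mechanism.
#' @return Named numeric vector of per-ligand biases (kcal/mol).
#' @export
scaling_ligand_bias <- function(table, factor = 0.7) {
  tab <- dplyr::filter(table, .data$factor == !!factor)
  if (nrow(tab) == 0) abort("`factor` not present in the scaling table.")
  wide <- tidyr::pivot_wider(tab, id_cols = "ligand",
                             names_from = "environment",
                             values_from = "dg_scaled")
  setNames(-(wide$bound - wide$free), wide$ligand)
}
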