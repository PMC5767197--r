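# Scoring predictions against experiment: IC50 conversion, Pearson R, MUE,
# and the two bootstrap protocols (Gaussian-parametric over computed errors
# and dataset resampling), plus the experimental-noise ceiling on R.

#' Convert an IC50 ratio to a relative binding free energy
#'
#' `ddG(L1 -> L2) = kT * log(IC50(L2) / IC50(L1))`: a ligand with a lower
#' IC50 than the reference binds more favourably (negative ddG). The values
#' telescope over ligand chains and are antisymmetric in their arguments.
#'
#' @param ic50_l1,ic50_l2 IC50 values (any common concentration unit).
#' @param temperature Assay temperature, K.
#' @return Relative binding free energy in kcal/mol (vectorised).
#' @examples
#' ic50_to_ddg(1, 10) # ~1.364 kcal/mol at 298 K
#' @export
ic50_to_ddg <- function(ic50_l1, ic50_l2, temperature = 298) {
  if (any(ic50_l1 <= 0) || any(ic50_l2 <= 0)) {
    abort("IC50 values must be positive.")
  }
  check_scalar_number(temperature, "temperature", positive = TRUE)
  kT(temperature) * log(ic50_l2 / ic50_l1)
}

#' Experimental relative free energies from an IC50 table
#'
#' @param ic50 Tibble with columns `ligand`, `ic50`.
#' @param reference Reference ligand identifier.
#' @param temperature Assay temperature, K.
#' @return Tibble with columns `ligand`, `exp_ddg` (vs the reference).
#' @export
experimental_ddg <- function(ic50, reference, temperature = 298) {
  if (!reference %in% ic50$ligand) abort("`reference` not in the IC50 table.")
  ref_ic50 <- ic50$ic50[ic50$ligand == reference]
  ic50 |>
    mutate(exp_ddg = ic50_to_ddg(ref_ic50, .data$ic50,
                                 temperature = temperature)) |>
    select("ligand", "exp_ddg")
}

#' Join computed estimates with experimental values
#'
#' @param estimates Tibble with columns `ligand`, `ddg_vs_ref`, `err`.
#' @param experimental Tibble with columns `ligand`, `exp_ddg`.
#' @return Tibble with columns `ligand`, `computed`, `computed_err`,
#'   `experimental` over the overlapping ligands.
#' @export
affinity_pairs <- function(estimates, experimental) {
  dplyr::inner_join(
    estimates |> select("ligand", computed = "ddg_vs_ref",
                        computed_err = "err"),
    experimental |> select("ligand", experimental = "exp_ddg"),
    by = "ligand"
  )
}

#' Pearson correlation between computed and experimental values
#'
#' @param pairs Tibble with columns `computed`, `experimental` (>= 3 rows).
#' @return Pearson product-moment correlation coefficient.
#' @export
pearson_r <- function(pairs) {
  if (nrow(pairs) < 3) abort("Pearson R needs at least 3 pairs.")
  if (sd(pairs$computed) == 0 || sd(pairs$experimental) == 0) {
    abort("Pearson R undefined: zero variance in one coordinate.",
          class = "fepnet_undefined_result")
  }
  cor(pairs$computed, pairs$experimental)
}

#' Mean unsigned error between computed and experimental values
#'
#' @param pairs Tibble with columns `computed`, `experimental` (>= 1 row).
#' @return MUE in kcal/mol.
#' @export
mue <- function(pairs) {
  if (nrow(pairs) < 1) abort("MUE needs at least one pair.")
  mean(abs(pairs$computed - pairs$experimental))
}

new_metric_report <- function(r, mues, n, protocol, n_boot, extra = list()) {
  structure(
    c(list(
      r_mean = mean(r), r_sigma = sd(r) %|na|% 0,
      mue_mean = mean(mues), mue_sigma = sd(mues) %|na|% 0,
      n_ligands = n, protocol = protocol, n_boot = as.integer(n_boot)
    ), extra),
    class = "metric_report"
  )
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report (%s, %d ligands, %d reps): R %.3f +/- %.3f, MUE %.3f +/- %.3f kcal/mol>\n",
    x$protocol, x$n_ligands, x$n_boot,
    x$r_mean, x$r_sigma, x$mue_mean, x$mue_sigma
  ))
  invisible(x)
}

#' Gaussian-parametric bootstrap of R and MUE
#'
#' Each replicate redraws every computed value from a Gaussian centred on
#' the estimate with its standard error as standard deviation, then
#' recomputes Pearson R and MUE against the fixed experimental values. The
#' means and standard deviations of the resulting distributions are the
#' reported metrics and their 1-sigma confidence intervals. With all
#' computed errors zero the Gaussians are degenerate and the report
#' collapses to the plain point estimates with zero sigma.
#'
#' @param pairs Tibble with columns `computed`, `computed_err`,
#'   `experimental`.
#' @param n_boot Number of replicates.
#' @param seed Integer seed.
#' @return A `metric_report`.
#' @export
bootstrap_parametric <- function(pairs, n_boot = 10000, seed = 1) {
  if (n_boot < 2) abort("`n_boot` must be >= 2.")
  if (nrow(pairs) < 3) abort("Need at least 3 pairs.")
  if (any(pairs$computed_err < 0)) abort("Negative computed errors.")

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n <- nrow(pairs)
  draws <- matrix(rnorm(n_boot * n,
                        mean = rep(pairs$computed, each = n_boot),
                        sd = rep(pairs$computed_err, each = n_boot)),
                  nrow = n_boot)
  exp_v <- pairs$experimental

  degenerate <- apply(draws, 1, sd) == 0 | sd(exp_v) == 0
  r <- rep(NA_real_, n_boot)
  point_r <- if (sd(pairs$computed) > 0 && sd(exp_v) > 0) {
    cor(pairs$computed, exp_v)
  } else NA_real_
  r[degenerate] <- point_r
  if (any(!degenerate)) {
    r[!degenerate] <- apply(draws[!degenerate, , drop = FALSE], 1,
                            cor, y = exp_v)
  }
  mues <- rowMeans(abs(sweep(draws, 2, exp_v)))

  new_metric_report(r, mues, n, "parametric", n_boot)
}

#' Dataset bootstrap of R and MUE
#'
#' Each replicate resamples whole (computed, experimental) pairs with
#' replacement to the original size and recomputes the metrics, mirroring
#' the resampling protocol used by benchmark organisers. Replicates whose
#' resample is degenerate (zero variance in either coordinate) are redrawn
#' and counted in `n_degenerate`.
#'
#' @inheritParams bootstrap_parametric
#' @return A `metric_report` with an extra `n_degenerate` element.
#' @export
bootstrap_dataset <- function(pairs, n_boot = 1000, seed = 1) {
  if (n_boot < 2) abort("`n_boot` must be >= 2.")
  if (nrow(pairs) < 3) abort("Need at least 3 pairs.")

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n <- nrow(pairs)
  r <- numeric(n_boot)
  mues <- numeric(n_boot)
  n_degenerate <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      cx <- pairs$computed[idx]
      ex <- pairs$experimental[idx]
      if (sd(cx) > 0 && sd(ex) > 0) break
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > 100 * n_boot) {
        abort("Dataset bootstrap cannot find non-degenerate resamples.")
      }
    }
    r[b] <- cor(cx, ex)
    mues[b] <- mean(abs(cx - ex))
  }
  if (n_degenerate > 0) {
    warn(sprintf("%d degenerate resamples were redrawn.", n_degenerate))
  }
  new_metric_report(r, mues, n, "dataset", n_boot,
                    extra = list(n_degenerate = n_degenerate))
}

#' Ceiling Pearson R under experimental noise
#'
#' Estimates the highest correlation any method could achieve given the
#' assumed uncertainty of the experimental measurements: each replicate
#' perturbs the experimental vector with Gaussian noise of standard
#' deviation `exp_sigma` and correlates it with the unperturbed vector.
#'
#' @param experimental Numeric vector of experimental relative free
#'   energies (kcal/mol), at least 3 values with non-zero spread.
#' @param exp_sigma Assumed experimental uncertainty, kcal/mol.
#' @param n_boot Number of replicates.
#' @param seed Integer seed.
#' @return A list with `mean` and `sigma` of the ceiling-R distribution.
#' @examples
#' ceiling_r(c(-2, -1, 0, 1, 2), exp_sigma = 0.4, n_boot = 200, seed = 1)
#' @export
ceiling_r <- function(experimental, exp_sigma = 0.4, n_boot = 10000,
                      seed = 1) {
  if (length(experimental) < 3 || sd(experimental) == 0) {
    abort("Ceiling R needs >= 3 experimental values with non-zero spread.",
          class = "fepnet_undefined_result")
  }
  if (exp_sigma < 0) abort("`exp_sigma` must be >= 0.")
  if (exp_sigma == 0) return(list(mean = 1, sigma = 0))

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n <- length(experimental)
  r <- vapply(seq_len(n_boot), function(b) {
    cor(experimental, experimental + rnorm(n, 0, exp_sigma))
  }, numeric(1))
  list(mean = mean(r), sigma = sd(r))
}
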