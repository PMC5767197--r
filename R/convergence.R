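# Convergence diagnostics for lambda-gradient timeseries: equilibration
# discard, thermodynamic integration, stationarity testing (augmented
# Dickey-Fuller), estimator consistency, and repeat recommendations.

#' Discard the equilibration portion of gradient timeseries
#'
#' Removes the first `floor(fraction * n)` samples of each lambda window
#' (so short windows with `fraction * n < 1` are untouched). The default of
#' 5% mirrors the customary equilibration discard before free energy
#' analysis.
#'
#' @param gradients Tibble with columns `lambda`, `sample_index`, `dudl`.
#' @param fraction Fraction of each window to discard, in \[0, 1).
#' @return The gradients tibble with early samples removed.
#' @examples
#' g <- simulate_gradients(1, n_lambda = 3, n_samples = 100, seed = 1)
#' nrow(discard_equilibration(g)) # 3 * 95
#' @export
discard_equilibration <- function(gradients, fraction = 0.05) {
  if (fraction < 0 || fraction >= 1) abort("`fraction` must lie in [0, 1).")
  gradients |>
    group_by(.data$lambda) |>
    arrange(.data$sample_index, .by_group = TRUE) |>
    filter(dplyr::row_number() > floor(fraction * n())) |>
    ungroup()
}

#' Thermodynamic integration estimate
#'
#' Trapezoidal integration of the per-window mean gradient over the lambda
#' grid.
#'
#' @param gradients Tibble with columns `lambda`, `dudl` (at least two
#'   distinct lambda values; duplicate windows are an error).
#' @return Free energy estimate in kcal/mol.
#' @examples
#' g <- tibble::tibble(lambda = rep(c(0, 0.5, 1), each = 2),
#'                     dudl = rep(c(0, 1, 2), each = 2))
#' ti_estimate(g) # integral of 2*lambda = 1
#' @export
ti_estimate <- function(gradients) {
  means <- gradients |>
    group_by(.data$lambda) |>
    summarise(mean_dudl = mean(.data$dudl), .groups = "drop") |>
    arrange(.data$lambda)
  if (nrow(means) < 2) abort("TI needs at least two lambda windows.")
  if (anyDuplicated(means$lambda)) abort("Duplicate lambda windows.")
  lam <- means$lambda
  mu <- means$mean_dudl
  sum(diff(lam) * (mu[-length(mu)] + mu[-1]) / 2)
}

# MacKinnon (2010) response-surface coefficients for the constant-only
# Dickey-Fuller tau distribution; critical value = b0 + b1/T + b2/T^2 + b3/T^3.
.adf_cv_table <- rbind(
  `0.01` = c(-3.43035, -6.5393, -16.786, -79.433),
  `0.05` = c(-2.86154, -2.8903, -4.234, -40.040),
  `0.10` = c(-2.56677, -1.5384, -2.809, 0)
)

adf_critical_value <- function(alpha, n_eff) {
  levels <- as.numeric(rownames(.adf_cv_table))
  cv <- apply(.adf_cv_table, 1, function(b) {
    b[1] + b[2] / n_eff + b[3] / n_eff^2 + b[4] / n_eff^3
  })
  if (alpha <= levels[1]) return(cv[1])
  if (alpha >= levels[length(levels)]) return(cv[length(cv)])
  stats::approx(log(levels), cv, xout = log(alpha))$y
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Fits the regression `diff(x)_t = a + g * x_{t-1} + sum phi_i diff(x)_{t-i}`
#' (constant, no trend) and returns the t statistic of `g`. The lag order is
#' chosen by AIC over `0:max_lag` on a common estimation sample, with
#' `max_lag = floor(12 * (n/100)^0.25)` by default; the chosen lag is then
#' refit on the longest usable sample. Critical values follow the MacKinnon
#' response surfaces for the constant-only case.
#'
#' @param x Numeric series (>= 20 observations).
#' @param max_lag Maximum augmentation lag (default Schwert rule).
#' @return A list with `statistic`, `lag`, `n_eff`, and `critical`
#'   (function of alpha).
#' @export
adf_statistic <- function(x, max_lag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 20) abort("ADF test needs at least 20 observations.")
  max_lag <- max_lag %||% floor(12 * (n / 100)^0.25)
  max_lag <- min(max_lag, n - 10L)

  dx <- diff(x)
  fit_adf <- function(p, common_start) {
    # rows t index dx; regression valid for t >= p + 1
    start <- max(common_start, p + 1L)
    idx <- start:length(dx)
    y <- dx[idx]
    X <- cbind(1, x[idx])          # constant + lagged level
    if (p > 0) {
      lags <- vapply(seq_len(p), function(i) dx[idx - i], numeric(length(idx)))
      X <- cbind(X, lags)
    }
    fit <- stats::lm.fit(X, y)
    k <- ncol(X)
    rss <- sum(fit$residuals^2)
    nn <- length(y)
    sigma2 <- rss / (nn - k)
    XtX_inv <- chol2inv(chol(crossprod(X)))
    se_g <- sqrt(sigma2 * XtX_inv[2, 2])
    list(stat = fit$coefficients[2] / se_g,
         aic = nn * log(rss / nn) + 2 * k,
         n_eff = nn)
  }

  aics <- vapply(0:max_lag, function(p) fit_adf(p, max_lag + 1L)$aic,
                 numeric(1))
  best_p <- (0:max_lag)[which.min(aics)]
  final <- fit_adf(best_p, best_p + 1L)

  list(
    statistic = unname(final$stat),
    lag = best_p,
    n_eff = final$n_eff,
    critical = function(alpha) adf_critical_value(alpha, final$n_eff)
  )
}

#' Stationarity flag for a gradient timeseries
#'
#' TRUE when the augmented Dickey-Fuller unit-root null is rejected at
#' level `alpha`, i.e. the series looks stationary; FALSE for series
#' consistent with a unit root (drifting, unconverged sampling). A
#' constant series is stationary by convention.
#'
#' @param x Numeric series of gradient samples (>= 20 values).
#' @param alpha Significance level in (0, 1); critical values are tabulated
#'   for 0.01-0.10 and clamped outside that range.
#' @param max_lag Maximum augmentation lag, see [adf_statistic()].
#' @return Logical flag.
#' @examples
#' set.seed(1)
#' stationarity_flag(rnorm(500))         # TRUE
#' stationarity_flag(cumsum(rnorm(500))) # FALSE (usually)
#' @export
stationarity_flag <- function(x, alpha = 0.05, max_lag = NULL) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  x <- as.numeric(x)
  if (length(x) < 20) abort("Stationarity test needs at least 20 samples.")
  if (sd(x) == 0) return(TRUE)
  res <- adf_statistic(x, max_lag = max_lag)
  res$statistic < res$critical(alpha)
}

#' Consistency check between two free energy estimators
#'
#' Flags a perturbation as converged when independent estimators (e.g. TI
#' and MBAR) agree to within `tol` kcal/mol.
#'
#' @param ti_dg,mbar_dg Free energy estimates in kcal/mol.
#' @param tol Agreement tolerance, kcal/mol.
#' @return A tibble with `ti_dg`, `mbar_dg`, `discrepancy`, `consistent`.
#' @examples
#' consistency_check(1.0, 1.3) # consistent, discrepancy 0.3
#' @export
consistency_check <- function(ti_dg, mbar_dg, tol = 0.5) {
  check_scalar_number(tol, "tol", positive = TRUE)
  tibble(
    ti_dg = ti_dg, mbar_dg = mbar_dg,
    discrepancy = abs(ti_dg - mbar_dg),
    consistent = abs(ti_dg - mbar_dg) <= tol
  )
}

#' Full convergence verdict for one perturbation
#'
#' Applies the equilibration discard, tests each lambda window for
#' stationarity, integrates the gradients by TI, and (when an externally
#' computed MBAR estimate is supplied) checks estimator consistency.
#'
#' @param gradients Tibble with columns `lambda`, `sample_index`, `dudl`.
#' @param mbar_dg Externally computed MBAR estimate (kcal/mol), or NA.
#' @param discard_fraction Equilibration fraction to drop per window.
#' @param alpha ADF significance level.
#' @param tol TI-MBAR agreement tolerance, kcal/mol.
#' @return A list of class `convergence_verdict`: `stationary_per_window`
#'   (tibble lambda/stationary), `all_stationary`, `ti_dg`, `mbar_dg`,
#'   `discrepancy`, `consistent`.
#' @export
convergence_report <- function(gradients, mbar_dg = NA_real_,
                               discard_fraction = 0.05, alpha = 0.05,
                               tol = 0.5) {
  g <- discard_equilibration(gradients, discard_fraction)
  per_window <- g |>
    group_by(.data$lambda) |>
    summarise(stationary = stationarity_flag(.data$dudl, alpha = alpha),
              .groups = "drop")
  ti <- ti_estimate(g)
  cc <- if (is.na(mbar_dg)) {
    tibble(discrepancy = NA_real_, consistent = NA)
  } else {
    consistency_check(ti, mbar_dg, tol = tol)
  }
  structure(
    list(
      stationary_per_window = per_window,
      all_stationary = all(per_window$stationary),
      ti_dg = ti, mbar_dg = mbar_dg,
      discrepancy = cc$discrepancy, consistent = cc$consistent
    ),
    class = "convergence_verdict"
  )
}

#' @export
print.convergence_verdict <- function(x, ...) {
  cat(sprintf(
    "<convergence_verdict: TI %.3f kcal/mol, %d/%d windows stationary%s>\n",
    x$ti_dg, sum(x$stationary_per_window$stationary),
    nrow(x$stationary_per_window),
    if (is.na(x$consistent)) "" else {
      sprintf(", TI-MBAR discrepancy %.3f (%s)", x$discrepancy,
              if (x$consistent) "consistent" else "inconsistent")
    }
  ))
  invisible(x)
}

#' Recommend additional repeats for a noisy edge
#'
#' Perturbations whose forward/backward hysteresis exceeds the tolerance
#' are candidates for repeat simulations, up to a total of `max_repeats`
#' runs per direction.
#'
#' @param hysteresis Forward/backward disagreement, kcal/mol.
#' @param repeats_done Repeats already run.
#' @param hysteresis_tol Acceptable hysteresis, kcal/mol.
#' @param max_repeats Total repeat budget per edge.
#' @return Integer count of recommended additional repeats.
#' @examples
#' repeat_recommendation(0.8, repeats_done = 1, hysteresis_tol = 0.5)
#' @export
repeat_recommendation <- function(hysteresis, repeats_done = 1,
                                  hysteresis_tol = 0.5, max_repeats = 3) {
  check_scalar_number(hysteresis_tol, "hysteresis_tol", positive = TRUE)
  if (hysteresis <= hysteresis_tol) return(0L)
  needed <- ceiling(hysteresis / hysteresis_tol) - 1
  as.integer(max(0, min(needed, max_repeats - repeats_done)))
}
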