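---
title: "Free energy network analysis: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free energy network analysis: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepnet)
library(dplyr)
```

## What this package models

An alchemical relative binding free energy study produces, for each edge of
a perturbation map, one or more directional estimates of
$\Delta\Delta G(L_1 \to L_2)$ in kcal/mol. `fepnet` takes those numbers —
not trajectories — and produces per-ligand relative binding free energies
versus a reference compound, convergence diagnostics, corrected variants,
and scored comparisons against IC50-derived experimental values. Everything
upstream of the numbers (force fields, sampling, MBAR internals, docking)
is deliberately outside the model: the package treats per-edge estimates as
exchangeable noisy measurements of an underlying consistent free energy
surface, which is exactly the assumption the network diagnostics are
designed to interrogate.

## The estimator

### Edges

For one unordered node pair, forward values $f_i$ and sign-flipped backward
values $-b_i$ are pooled into a single sample. The edge weight is the
pooled mean, the edge error the pooled standard error
($s/\sqrt{n}$, with $s$ the sample standard deviation, ddof 1), and the
hysteresis $|\bar f - \overline{(-b)}|$. Pooling rather than modelling two
direction-specific populations is the simplest estimator consistent with
averaging "forward and reversed backward" runs; hysteresis is kept as a
diagnostic rather than subtracted, because systematic direction asymmetry
in well-converged runs is indistinguishable from noise at typical repeat
counts. A single-run edge has standard error 0 (with a warning); the error
floor below keeps its weight finite downstream.

### Paths

With the antisymmetric weighted adjacency $w_{ij}$ and symmetric error
matrix $\epsilon_{ij}$, every simple path $p$ from a ligand to the
reference gives $\Delta g_p = \sum w$ and
$e_p = \sqrt{\sum \epsilon^2}$. Paths are combined by a normalized
inverse-error weighted mean:

$$u_p = 1/\max(e_p, \text{floor}), \quad \omega_p = u_p / \textstyle\sum u,
\quad \Delta\Delta G = \sum \omega_p \Delta g_p, \quad
E = \sqrt{\textstyle\sum \omega_p^2 e_p^2}.$$

Two deliberate choices sit here:

* **Normalization.** The combination formulas as sometimes printed in the
  literature (a sum of $\omega \Delta g / \epsilon$ with
  $\omega = \sum 1/e$, and $E = \sqrt{\sum \omega e}$) are not
  dimensionally a weighted mean. The package defaults to the normalized
  reading above — which satisfies the intended property that smaller-error
  paths contribute more, is bounded by the range of the path values, and is
  invariant to rescaling all errors — and retains the literal formulas as
  `mode = "paper_literal"` / `err_mode = "paper_literal"` for audit.
* **Ignored path correlations.** Paths sharing edges are correlated; the
  error propagation ignores this, as the field's practice does. $E$ is
  therefore an optimistic error for dense networks. The cycle-closure
  report is the counterweight: closure magnitudes expose inconsistency the
  per-ligand error understates.

The error floor (default $10^{-6}$ kcal/mol) exists solely to keep weights
finite on noiseless (synthetic, or single-run) networks; it preserves the
zero-noise identity to better than $10^{-10}$ kcal/mol. Path enumeration is
capped (default 10,000 paths, path length at most the node count), taking
shortest paths first: simple-path counts grow factorially, while real
perturbation maps are small and sparse enough that the caps never bind.

### Binding modes

Alternative poses of one compound are collapsed by exponential averaging
$\Delta\Delta G = -k_BT \ln \sum_k e^{-\Delta\Delta G(BM_k)/k_BT}$,
evaluated through a log-sum-exp shift so hopeless modes cannot underflow
into NaN. The result lies in $[\min_k - k_BT\ln N, \min_k]$. Exponential
averaging defines no error rule; the dominant (minimum) mode's error is
reported, which is exact in the well-separated limit and mildly optimistic
for near-degenerate modes. $k_B = 0.0019872041$ kcal/(mol K) and
$T = 298$ K by default, matching the simulation thermostat convention.

### Reference anchoring

With multi-mode reference compounds, paths anchor on the reference's
lexicographically first mode node and all per-ligand values are shifted so
the reference's own mode-collapsed estimate is exactly $(0, 0)$. In the
noiseless case re-referencing shifts every estimate by a constant, which
the tests assert exactly.

## Corrections

The charge-scaling correction
$\Delta\Delta G_{\text{scaled}}(L_1,L_2) = \Delta G(L_1,\text{free}) +
\Delta G(L_2,\text{bound}) - \Delta G(L_1,\text{bound}) -
\Delta G(L_2,\text{free})$
is applied **per network edge** before path combination, not post hoc per
ligand: the correction is defined pairwise, and edge-level application
keeps the network representation (and its cycle diagnostics) consistent.
Factors follow the charge rule — 0.7 when the perturbation conserves net
charge, 0.5 when it changes it. Under a single factor, corrections
telescope around every cycle exactly; under the mixed rule they need not,
and that residual deliberately surfaces in the cycle-closure report rather
than being hidden. The grid report scores each candidate factor by R and
MUE and flags the MUE-minimising and R-maximising factors, but never picks
a "best tradeoff" automatically — that judgement stays with the analyst.

## Convergence diagnostics

* **Equilibration discard**: the first $\lfloor 0.05 n \rfloor$ samples of
  each λ window (configurable).
* **Thermodynamic integration**: trapezoidal rule over the per-window mean
  gradients. Trapezoid (not spline) is the minimal defensible quadrature
  and admits exact oracle tests: it is exact for linear gradients, and for
  $3\lambda^2$ on an 11-point uniform grid its error is exactly
  $h^2/12 \cdot 6 = 0.005$.
* **Stationarity**: an augmented Dickey–Fuller test per λ window
  (constant, no trend; lag order by AIC up to
  $\lfloor 12 (n/100)^{1/4}\rfloor$, the common defaults), with MacKinnon
  response-surface critical values. The flag is TRUE — stationary — when
  the unit-root null is rejected at $\alpha = 0.05$; constant series are
  stationary by convention. The implementation is native to the package
  and is validated behaviourally: at $n = 2000$ it accepts essentially all
  white-noise series and rejects $\geq 90\%$ of random walks, with a
  rejection rate under the unit-root null of about 7% (nominal 5%, the
  excess from AIC lag selection).
* **Estimator consistency**: $|TI - MBAR| \leq 0.5$ kcal/mol flags a
  perturbation as converged. MBAR estimates are inputs; the package checks
  them, it does not compute them.
* **Repeat recommendation**: edges whose hysteresis exceeds tolerance get
  $\min(\lceil h/\text{tol}\rceil - 1, 3 - \text{done})$ additional
  repeats, reflecting the "repeat up to three times" practice.

## Scoring

Experimental relative affinities derive from IC50 ratios,
$\Delta\Delta G = k_BT \ln(\mathrm{IC50}_{L_2}/\mathrm{IC50}_{L_1})$, at an
assumed assay temperature of 298 K (the assay temperature is rarely
reported; it is configurable). Two bootstrap protocols quantify metric
uncertainty:

* **parametric** (default 10,000 reps): each computed value is redrawn from
  $\mathcal N(\hat x, \hat\sigma)$ and R/MUE recomputed; with all
  $\hat\sigma = 0$ the report collapses exactly to the point estimates.
* **dataset** (default 1,000 reps): whole pairs resampled with replacement,
  the organisers' convention in blinded challenges; degenerate resamples
  are redrawn and counted.

Reported "1σ confidence intervals" are the standard deviations of the
bootstrap distributions, not percentiles, matching the mean-and-1σ
reporting convention. The **ceiling R** construction perturbs the
experimental vector with $\mathcal N(0, \sigma_{\exp})$ noise
($\sigma_{\exp} = 0.4$ kcal/mol by default) and correlates it with itself;
its mean over replicates is the highest correlation any method should be
expected to reach on that affinity spread.

## The synthetic-data generator

The generator defines the study conditions under which the analysis is
validated:

* **Truth**: per-ligand free energies uniform over a `dg_span` window
  (default 5 kcal/mol, a realistic lead-series spread);
  $\lceil \text{fraction} \cdot n \rceil$ ligands carry net charge −1;
  mode counts uniform in `1:max_modes`. Per-mode node free energies are
  shifted so that Boltzmann averaging over a ligand's modes returns its
  true value *exactly* — the mode split redistributes probability across
  poses without creating free energy, which makes the zero-noise
  end-to-end identity exact rather than approximate.
* **Topology**: a uniform random spanning tree (random Prüfer sequence)
  plus uniformly sampled chords. Connectivity is guaranteed, and the
  cycle-space dimension equals the chord count, mirroring hand-designed
  perturbation maps that maximise simple cycles for cross-validation.
* **Edges**: per repeat, one forward and one backward run; Gaussian noise
  `edge_sigma`, direction-specific hysteresis noise (hysteresis is treated
  as statistical disagreement, not a fixed offset), and a systematic
  `charge_change_bias` oriented towards the charged endpoint of
  charge-changing edges — the observed failure mode of charge-changing
  perturbations. Backward runs are stored with the backward morph's sign,
  matching real file provenance.
* **Gradients**: a fixed quadratic mean curve $1 + \lambda - \lambda^2$
  rescaled so its trapezoidal integral equals the target (closed-form
  oracle for TI tests), stationary AR(1) noise, and an optional
  linear-in-time drift that makes windows non-stationary. The AR(1)
  marginal amplitude `noise_sigma` defaults to 1 kcal/mol, a typical
  gradient fluctuation scale, and 0 gives the exact noiseless limit.
* **Experiment**: IC50s generated by inverting the conversion with
  $\mathcal N(0, 0.4)$ kcal/mol assay noise, the conventional estimate of
  IC50 uncertainty.
* **Scaling tables**: per-ligand polarisation susceptibilities (roughly
  twice as large for charged ligands), entries linear in $(1-f)$, larger
  in the bound leg. `scaling_ligand_bias()` converts a table into the
  per-ligand systematic error that a "polarisation mechanism at factor f"
  study would show, which is how the grid report's self-consistency is
  exercised: data generated with the factor-0.7 mechanism have their
  ensemble-averaged MUE minimised at 0.7. Over a 10-study ensemble the
  averaged MUE curve identifies the generating factor cleanly; individual
  small studies can flip the argmin to a neighbouring factor by sampling
  noise, which is a property of 9-ligand datasets, not of the estimator.

What the generator does **not** emulate: correlated errors between edges
sharing a transformed substructure, heavy-tailed or bimodal repeat
distributions (repeat noise is assumed Gaussian, as nothing in standard
practice constrains it better), λ-window-dependent noise, and finite-time
systematic bias in the underlying estimators. Passing tests therefore
demonstrate the *analysis* is correct and self-consistent under its stated
noise model — not that any particular simulation campaign is converged.

## Problem sizes and numerical choices

The validation suite runs studies of 8–10 ligands with 3–4 chords and 2–3
repeats — the scale of the blinded-challenge subsets this kind of analysis
is used on — and 20-study ensembles for recovery statistics; stationarity
operating characteristics use 100–500 series of 2000 samples. At the
reference conditions (edge σ = 0.3 kcal/mol, 3 repeats, tree + 3 chords)
ground-truth recovery achieves RMSE ≈ 0.13–0.16 kcal/mol and R > 0.99
against truth, comfortably inside the σ = 0.3 target. Degenerate inputs are
handled explicitly: empty path sets and disconnected pairs are signalled,
zero-variance metric inputs raise classed conditions rather than NaN,
single-run edges warn, and all generators restore the global RNG state so
seeded calls are pure.

## Known limitations

* Path-combination errors ignore inter-path correlation (shared edges);
  use cycle closures alongside $E$.
* The mode-collapsed error is the dominant mode's error, optimistic for
  near-degenerate modes.
* The literal combination formulas are preserved only for audit; numbers
  produced with `mode = "paper_literal"` are not on a meaningful scale.
* The ADF critical values are tabulated at the 1/5/10% levels and
  interpolated between; `alpha` outside [0.01, 0.10] is clamped to the
  tabulated range.
* No maximum-likelihood or least-squares network estimator is provided —
  the path-weighting scheme plus its audit variant is the point — and no
  MBAR/BAR implementation is included; per-edge estimates are inputs.
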