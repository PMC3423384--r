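---
title: "Dual-marker Bayesian assignment: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-marker Bayesian assignment: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualorigin)
```

## The assignment model

`dualorigin` infers the breeding-ground origin of an individual bird from
two intrinsic markers measured at capture: the stable-hydrogen isotope ratio
of a feather grown on the breeding grounds (δ²H_f, permil vs VSMOW) and a
vector of genetic admixture coefficients Q over K population clusters. The
inference is per raster cell over the species range.

**Isotope likelihood.** A precipitation isoscape δ²H_p is rescaled into
feather space through an age-specific linear calibration

$$\delta^2H_f = \beta_0 + \beta_1\,\delta^2H_p + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2),$$

fitted by ordinary least squares on known-origin birds
(`fit_calibration()`). Second-year (SY) and after-second-year (ASY) birds
are always fitted independently — their feathers integrate different molt
histories, so they get separate isoscapes; no pooled model is offered. For
a bird with feather value $y$, the likelihood of cell $c$ is the normal
density $N(y;\, \mu(c), \sigma)$ with $\mu(c)$ the calibrated feather
isoscape, renormalized to sum to one over the range mask
(`likelihood_surface()`).

**Genetic prior.** The admixture coefficient $q_k$ is read as the
probability that the individual originates from cluster $k$. That
cluster-level mass is spread *uniformly* over the cluster's cells — the
maximum-entropy completion, since the genetic marker carries no information
about position within a cluster. A consequence worth stating prominently:
two clusters with equal $q_k$ contribute equal total mass, so the *larger*
cluster has the *lower* per-cell prior. Spatial weighting within clusters
(by abundance, kernel smoothing) would be an alternative completion; uniform
spreading is the only one implemented.

**Posterior and regions.** The posterior is the cell-wise product of
likelihood and prior, renormalized (`posterior_surface()`). Isotope-only
assignment is the same computation under a uniform prior — normalizing the
likelihood makes that a literal special case rather than a parallel code
path. Posteriors are thresholded by odds ratio: r:1 odds correspond to the
credible level $r/(r+1)$ (67% at 2:1, 75% at 3:1), and the origin region is
the smallest set of highest-probability cells whose cumulative mass reaches
that level (`threshold_region()`). Region sizes are raster-cell counts; the
headline effect measure is the fold-change in cell count from adding the
prior.

### Assumptions

* The calibration is linear and its residual spread is homoscedastic and
  normal; σ is stationary across the range and across years.
* The feather assayed was grown at the breeding/natal site (true for the
  first primary in the motivating species), so the isotope signal is an
  origin signal.
* Q vectors come from an upstream clustering run (e.g. STRUCTURE) whose
  clusters can be drawn on a map; the package consumes, never recomputes,
  them.
* Genetic signal is natal. For dispersers the two markers disagree by
  construction; the prior floor (below) keeps such birds assignable.

## Tunable parameters

| Parameter | Units | Default | Where | Why this default |
|---|---|---|---|---|
| `sigma` | permil | calibration residual SD | `assign_birds()` | the model's own estimate of feather-vs-isoscape scatter; override to inflate for isoscape model error, which the calibration alone does not capture |
| `odds` | — | `c(2, 3)` | `assign_birds()` | the two conventional risk/resolution trade-offs (67% and 75% regions) |
| `floor_eps` | fraction | 0.01 | `build_prior_surface()` | mixes 1% uniform mass over the range so a disperser whose feather signal lies outside its genetic cluster is never given an identically zero posterior; small enough to leave informative priors essentially unchanged |
| Q sum tolerance | — | 0.02 | `read_q_matrix()` | absorbs rounding in published admixture tables; accepted rows are renormalized to sum exactly 1 |
| buffer cutoffs | km | 200 / 400, inclusive | `containment_class()` | the standard validation buffer classes; distances are great-circle (sphere radius 6371 km) from the capture point to selected cell centers |
| `nominal_cell_area_km2` | km² | 20 | `grid_spec()` | reporting constant only; all area arithmetic is in cell counts, since geographic cells vary in true area |

## Numerical and procedural choices

* **Grid registration.** Row 1 is the northernmost row; cell (1, 1)'s
  center is the grid origin; cells are enumerated row-major. Capture
  coordinates map to the nearest cell center, with exact boundary ties
  resolved to the northern/western cell — deterministic and
  order-independent.
* **Likelihood underflow.** Normal densities are computed in log space and
  shifted by their maximum before exponentiation, so an observation far
  from every cell mean still yields a proper (if diffuse) surface instead
  of an all-zero one.
* **Region ties.** All cells exactly tied with the last included cell enter
  the region. The slight overshoot of captured mass that ties (or the final
  discrete step) cause is recorded in `captured_mass`, not hidden.
* **Residual SD** uses the unbiased n − 2 denominator.
* **Credible regions are cumulative-mass sets** (smallest prefix of the
  probability-sorted cells reaching r/(r+1)), matching the "upper 67% of
  probabilities of origin" reading; a per-cell density cutoff would be the
  other construction and is not offered.
* **Degenerate inputs** fail loudly: fewer than 3 usable calibration
  samples, a zero-variance predictor, σ ≤ 0, an empty range mask,
  mismatched grids, and a likelihood × prior product that is identically
  zero (reported with the bird's id) are all errors, not warnings.
* **Zero-probability guard.** `chi_square_coverage()` delegates to the
  standard Pearson test without continuity correction, which is exactly the
  two-cell (O − E)²/E sum.

## The synthetic world

`make_world()` + `simulate_birds()` generate the study conditions every
test runs under. The generator emulates the geographic complementarity the
method exploits: precipitation deuterium interpolates linearly in latitude
(−140 permil at the northern edge to −30 at the southern, the realistic
continental orientation and span), and K genetic clusters are contiguous
longitudinal bands of near-equal width. Birds draw a uniform natal cell
within their cluster; feather values follow the generative calibration
(ASY: β₀ = −20, β₁ = 0.9, σ = 8 permil; SY: −25, 0.95, 10); Q vectors are
Dirichlet with concentration 10 on the natal cluster and 1 elsewhere, which
at K = 5 gives mean home-cluster membership ≈ 0.71 — the middle of the
range published admixture tables report. With `dispersal_fraction > 0`, a
bird's capture cluster (and coordinates) move, but its feather value and Q
stay natal, reproducing the marker discordance dispersal causes in real
cohorts. All randomness flows through the single config seed; cohorts are
bit-identical across runs and no global RNG state leaks.

What the generator does **not** emulate: real coastline/range geometry,
longitudinal structure in the isoscape, spatially varying σ, irregular and
overlapping cluster shapes, hybrid zones, uneven sampling across locales,
and microsatellite genotypes themselves (Q is simulated directly). Passing
tests therefore demonstrate the *machinery* is correct and calibrated under
the model's own assumptions — not that any particular field data set meets
those assumptions.

## Problem sizes and test design

The standard synthetic study used by the test suite and the acceptance
script is a 100 × 120 grid (12,000 cells), K = 5, 200 calibration birds and
500 query birds, no dispersal — large enough for stable coverage and
fold-change estimates, small enough to run in seconds. Under it the
2:1 isotope-only regions contain the true natal cell at a rate a little
above the nominal 67% (tie inclusion and the final discrete cell overshoot
the target mass; range-edge truncation adds a little more), which is why
the calibration checks accept coverage in [0.62, 0.80] at 2:1 and
[0.70, 0.87] at 3:1 rather than a point value. Unit tests check exact
arithmetic against closed-form oracles (hand Bayes, longhand OLS, explicit
brute-force region search, the two-cell χ² formula) and statistical
behaviour against calibrated bounds (binomial bands for coverage,
replicate-aggregate CI coverage for parameter recovery, since any single
95% interval misses 5% of the time by design).

## Known limitations

* GeoTIFF input/output is not provided; rasters travel as ESRI ASCII grids
  and cluster geographies as GeoJSON or labelled ASCII rasters.
* One isotope only; multi-isotope likelihoods are out of scope.
* The prior spreads cluster mass uniformly; abundance-weighted or smoothed
  completions are not implemented.
* Assignment is range-restricted and raster-based; no continuous-surface
  assignment.
* Inter-annual isoscape variance is not modelled; inflate `sigma` manually
  if it matters for your system.
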