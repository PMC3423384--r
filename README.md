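# dualorigin

Bayesian dual-marker assignment of migratory birds to their breeding-ground
origins.

## The problem

Linking the wintering (or stopover) grounds of a migratory bird to the
breeding area it came from is a central problem in avian ecology and
conservation. Two intrinsic markers are widely used, and they are
geographically complementary in North America:

* **Feather stable-hydrogen isotopes (δ²H_f).** Growing-season precipitation
  δ²H (δ²H_p) varies along broad *latitudinal* clines. A feather grown on
  the breeding grounds records the local value, so comparing a bird's δ²H_f
  to a calibrated "feather isoscape" constrains its origin in latitude — but
  says little about longitude.
* **Genetic admixture coefficients (Q).** Population genetic structure in
  northern temperate birds is predominantly *longitudinal*. Bayesian
  clustering of microsatellite genotypes (e.g. STRUCTURE) summarizes each
  individual as a vector of membership fractions across K genetic clusters —
  informative about longitude, vague about latitude.

`dualorigin` combines the two through Bayes' theorem. For a bird with
feather value `y` and admixture vector `Q`, the posterior probability that
raster cell `c` is its origin is

```
P(c | y, Q)  ∝  N(y; μ(c), σ)  ×  π_Q(c)
```

where `μ(c) = β₀ + β₁·δ²H_p(c)` is the age-specific calibrated feather
isoscape (β₀, β₁ fitted by OLS regression of known-origin feather values on
the precipitation isoscape; σ defaults to the calibration residual SD), and
the prior `π_Q(c)` gives each genetic cluster k total mass `q_k`, spread
uniformly over the cluster's cells (plus a small uniform floor so dispersers
are never zeroed out).

The posterior is thresholded into a binary **origin region** by odds ratio:
r:1 odds that the bird truly originated inside the mapped region correspond
to the smallest set of highest-probability cells holding r/(r+1) of the
posterior mass — the upper 67% at 2:1 odds, 75% at 3:1. Region sizes are
reported as raster-cell counts, and the improvement from the genetic prior
as the fold-change `cells(no prior) / cells(prior)`.

The package provides the full workflow — age-specific isoscape calibration,
likelihood/prior/posterior surfaces, odds-ratio regions, and a validation
toolkit (containment and 200/400 km buffer classes, per-locale area
summaries, χ² tests of observed vs nominal coverage, accuracy by method) —
plus a seeded synthetic-world generator that emulates the latitudinal
isoscape × longitudinal clusters geometry so every stage can be exercised
without field data. Rasters are ESRI ASCII grids; cluster geographies are
GeoJSON polygons or labelled rasters; all tabular input/output is CSV.

## Worked example

```r
library(dualorigin)

# a synthetic world: 100 x 120 grid, latitudinal isoscape, K = 5 bands
world <- make_world(world_config(seed = 1))
cal   <- simulate_birds(world, 40, "ASY", prefix = "cal")
model <- fit_calibration(cal, world$precip, "ASY")
model
#> <calibration_model ASY> d2Hf = -22.004 + 0.8769 * d2Hp, sigma = 8.271 permil (n = 200, R2 = 0.918)

world$config$seed <- 2L
birds <- simulate_birds(world, 100, "ASY")
records <- assign_birds(
  birds[1:3, ], list(ASY = model), world$precip,
  qtab = tibble::tibble(sample_id = birds$sample_id[1:3], q = birds$q[1:3]),
  clusters = world$clusters, odds = c(2, 3)
)
dplyr::select(records, sample_id, method, odds, n_cells, fold_vs_no_prior)
#>    sample_id     method        odds n_cells fold_vs_no_prior
#>  1 bird_ASY_0001 isotope_only     2    2040            NA
#>  3 bird_ASY_0001 bayes            2     648             3.15
#>  4 bird_ASY_0001 bayes            3     888             2.70
#>  ...
```

The calibration recovers the generating transfer function
(β₀ = −20, β₁ = 0.9, σ = 8 within sampling error). For bird 1, the
isotope-only 2:1 region spans 2040 cells — an east–west band of matching
latitude — while the genetic prior cuts it to 648 cells, a 3.15-fold gain in
spatial resolution; `containment` records whether the bird's capture cell
fell inside its region. `validate_assignments()` rolls a full cohort into
accuracy, per-locale area and χ² coverage tables, and `autoplot()` maps any
surface or region.

A command-line pipeline (`inst/cli/dualorigin`) exposes the same workflow as
`simulate`, `calibrate`, `assign` and `validate` subcommands.

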