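---
title: "Models and methods behind srcscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srcscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srcscape)
```

srcscape couples three layers: a seeded synthetic-landscape generator, a
spatially explicit economic simulation of land-use decisions with endogenous
markets, and simplified ecosystem-service and biodiversity assessments whose
outputs feed a bundle analysis. This vignette explains each model, the
parameters that matter, the numerical choices, and what the synthetic
landscapes can and cannot tell you about real regions.

## The synthetic landscape generator

`generate_landscape()` produces every layer the downstream models consume on
one grid (default 500 m cells; a 5 km analysis buffer is then exactly ten
cells). All continuous fields are filtered Gaussian noise: white noise is
smoothed with a Gaussian kernel of scale `autocorr_range_cells / 2` on a
padded grid, standardized, and rescaled affinely to the documented range, so
their marginals are whatever the smoothing produces (near-Gaussian,
truncated by clipping) — no claim is made about the true distribution of,
say, soil quality in any particular watershed.

The generator emulates a Central-European low-mountain watershed with a
strong terrain organisation:

* **Elevation** spans 70–1214 m; annual precipitation rises (`+0.65 mm/m`)
  and April–July temperature falls (`-0.0065 K/m`) with elevation, each with
  an independent autocorrelated residual. May–June precipitation is a fixed
  18% share of the annual sum; USLE rainfall erosivity is derived from
  annual precipitation at `0.0788 (MJ mm)/(ha h a)` per mm, a common German
  regression slope.
* **Land cover** is sliced from an elevation-coupled autocorrelated field at
  the cumulative class proportions, in the order the proportions are given:
  cropland and settlements occupy the lowlands, grassland the intermediate
  belt and forest the uplands, the layout of the kind of region this
  pipeline addresses (crop production on the loess lowlands, forestry in the
  mountains). Class counts hit the requested proportions exactly, up to
  rounding.
* **Soils**. The soil quality index spans 30–90 and profile available water
  capacity 140–220 mm, deliberately *moderate* ranges: the arable land of
  such regions is comparatively homogeneous plain farmland, and the relative
  weight of soil versus transport-cost heterogeneity in the land-use model
  depends directly on these spreads. The volumetric AWC layer is profile
  AWC divided by rooting depth.
* **Districts** are `n_districts` rectangular blocks (administrative
  boundaries are not reproducible synthetically). District-level crop
  yields scale with the district's mean soil quality plus independent
  noise. This matters: the crop-yield downscaling divides by the district
  mean potential, so if district yields were independent of district soil
  quality, downscaling would flatten the landscape-wide yield–quality
  relation and the economic model would misorder soils.
* **CHP plants** (default 15, the count in the watershed the model
  emulates) are sampled from settlement and cropland pixels — wood-chip
  consumers sit in towns and the agricultural lowlands, not in upland
  forest. The default capacity in the examples and tests is sized so that
  the standard demand scenario converts a few percent of the total area,
  the order of magnitude a regional CHP fleet demands.

Everything is deterministic for a fixed seed (`withr::with_seed`, one RNG
stream consumed in a fixed order).

What the generator does *not* emulate: road networks (transport distances
are Euclidean), real administrative geometry, land-cover fragmentation
statistics of CORINE data, within-year weather, or any correlation between
soil quality and elevation. Passing tests on these landscapes therefore
demonstrate that the *mechanisms* (soil sorting, plant proximity, demand
response, service trade-offs) operate and that the code computes its models
correctly — not that any number matches a particular real region.

## Site-specific yields

**Poplar SRC yield.** The regression
`yield = a4 * (a1*C + a2*P*SQI + a3*T/AWC)^a5` gives the biomass of a
rotation from the rotation cycle `C` (years), May–June precipitation `P`
(mm), soil quality index `SQI`, April–July mean temperature `T` (°C) and
available water capacity `AWC` (mm); `a4` and `a5` are quadratic in planting
density `N`. Defaults are the published values for the poplar clone Max
(`a1 = 1.569`, `a2 = 4e-4`, `a3 = -23.198`, `N = 9446`, `C = 5.5`).

Two readings of this formula are genuinely ambiguous in its typeset source
and both are carried as options:

* the third term: `a3*T/AWC` (default) versus `a3*T*AWC`
  (`t_over_awc = FALSE`). With the published coefficient signs and
  magnitudes the product form makes the inner term negative for every
  realistic site, so the quotient form is the default;
* the output unit: `src_yield(output = "annual")` (default) divides the
  regression value by `C`, reading it as a rotation total. At a
  representative site (P = 150 mm, SQI = 40, T = 13 °C, AWC = 150 mm) this
  gives 6.6 t dry matter/ha/a — a plausible poplar increment — whereas the
  raw value, 36.2, is not believable as an annual increment.
  `output = "rotation"` returns the raw regression value.

Sites whose inner term is non-positive get yield 0 with a warning rather
than a complex-power error.

**Annual crops.** One aggregate commodity. Pixel yield is the district
yield scaled by the pixel's yield potential relative to the district
arithmetic-mean potential; the potential layer is the soil quality index
(the generator has no separate potential map, and the two are conceptually
close).

## The economic simulation

Each cropland pixel is one profit-maximising agent choosing among SRC,
annual cropping and fallow. Net profit is revenue minus cost per hectare
and year: for SRC, `price * yield - production cost - rate * yield *
distance` to the chosen plant; annual crops carry production cost only
(they are marketed locally); fallow earns an area payment. Under one
regional wood-chip price the nearest plant wins; under local per-plant
prices the plant with the best per-tonne margin wins; ties go to the lowest
plant id. Exact profit ties resolve to ANNUAL, then SRC, then FALLOW — the
cultivation status quo wins a tie, and SRC wins a tie against idling land.
All agents update synchronously at each candidate price.

**Price formation.** Demands are perfectly inelastic exogenous quantities;
scenarios scale the wood-chip demand (defaults 1/2/4/8 for
standard/medium/high/very-high). `clear_market()` first runs a damped
multiplicative tatonnement `p <- p * (D/S)^lambda` with decaying damping and
price bounds. Because supply is a step function of price (each agent enters
at its *reservation price*, where SRC profit equals its best alternative),
the tatonnement can chatter on a step without entering the tolerance band;
the solver then switches to an exact pass: for any annual price the SRC
market is cleared by sorting reservation prices and picking the supply step
closest to demand, and the annual price is bracketed by bisection on its
monotone excess demand. Returned decisions are always best responses to the
returned prices, so no agent can gain by unilateral deviation — the
epsilon-stability check `equilibrium_stability()` returns at most floating
error.

**Corners.** With inelastic demands a configuration can be jointly
infeasible (SRC and annual demand together exceeding the land base). The
equilibrium then has a price at its bound with unmet demand; this is
returned as converged with `at_corner = TRUE` rather than as an error —
economically it is the "imports fill the gap" regime. Genuine
non-convergence (e.g. demand falling inside a one-agent supply step wider
than the tolerance band) aborts with the price trajectory attached.

**Calibration.** `calibrate_annual_demand()` bisects the annual demand
until the simulated baseline (zero SRC demand) reproduces target cultivated
and fallow shares of cropland (defaults 85% / 15%, a set-aside-era
baseline), then returns the cleared supply as the canonical demand. The
bisection runs the exact solver directly (`max_iter = 0`) so the
share–demand relation steps only by the one-agent granularity `1/n`; the
share tolerance (default 0.01) cannot meaningfully be tighter than that
step.

**EFA policy scenarios.** `allocate_efa()` converts
`ceiling(fraction * n_cropland)` pixels (default fraction `0.05/0.3` =
16.67%, the CAP greening arithmetic with SRC weighting factor 0.3) by
ascending or descending soil quality, ties on pixel id. The mandated SRC
output is sold at the equilibrium price: it reduces the demand facing the
remaining agents, whose markets are then cleared normally. Whether EFA
output should instead receive a fixed price is an open design point; the
cleared-price choice is flagged in the configuration.

**Parameter levels.** Production costs (300 / 1100 EUR/ha/a for SRC /
annual), the fallow payment (100 EUR/ha/a) and the transport rate
(1.0 EUR/t/km, farm tractor-and-trailer haulage of fresh chips over the
few-kilometre hauls that dominate deliveries) are documented plausible
defaults for a German commercial setting. The comparative statics of the
model — who converts first, where, and how the area responds to demand — do
not depend on their absolute levels, and no acceptance check does either.

## Ecosystem services and biodiversity

These are simplified, published-form models — deliberately *not* ports of
any specific InVEST or GLOBIO release. They preserve the structure and
directionality of the respective model families with per-class parameter
tables the user can replace.

* **Carbon**: class-wise densities over four pools (aboveground,
  belowground, soil, dead), times area. SRC stores more than the cropland
  it replaces, forests most.
* **Flow routing**: a D8 graph on the elevation layer; closed depressions
  are filled by priority flood with a tiny epsilon gradient so every
  interior cell keeps a strictly lower neighbour (the graph is acyclic by
  construction); gradient ties break on a fixed neighbour order (N, NE, E,
  SE, S, SW, W, NW). Border cells without a lower neighbour drain off-grid.
* **Phosphorus**: each pixel emits its class export coefficient times area;
  loads are attenuated multiplicatively by the filtering efficiency of
  every pixel traversed downstream (a pixel does not filter its own
  emission). Export is attributed to the emitting pixel; retention to the
  filtering pixel; emitted = exported + retained to floating precision.
* **Sediment**: USLE `A = R*K*LS*C*P` per pixel with `LS` from the classic
  slope/length relation at the 22.13 m reference plot length (the length
  exponent steps with slope class); routing as for phosphorus with trap
  efficiencies. Reported retention adds the avoided on-pixel erosion
  `R*K*LS*(1-CP)`; the routed mass balance closes on the generated loads.
  Hydrological runoff weighting of loads is deliberately omitted — the
  precipitation layer is available if a user wants to add it as a
  multiplier.
* **MSA**: the pixel mean species abundance is the product of five pressure
  factors in [0, 1] — land use (undisturbed = 1, SRC = 0.2, intensive
  cropland = 0.1), habitat fragmentation (piecewise in patch area,
  4-neighbour components of the natural classes), infrastructure proximity
  (distance to settlement pixels, standing in for the road network),
  population density, and N-deposition exceedance of a critical load
  (default 15 kg N/ha/a). The product is bounded by its smallest factor and
  adding any pressure can only lower it. The non-land-use lookup tables are
  implementer defaults in the spirit of the model family; only the SRC
  land-use value 0.2 (and undisturbed = 1) are fixed points of the method.

Under the default tables, converting cropland to SRC weakly raises carbon
and regional MSA and weakly lowers watershed P and sediment export — the
directional pattern the coupled analysis is designed to expose.

## Bundles and their drivers

`ess_matrix()` extracts six per-pixel services (carbon, P retention, P
export, sediment retention, sediment export, MSA). For clustering the
matrix is z-scaled — the scale-free metric; the max-to-100% normalisation
(`normalize_services(mode = "max")`, optionally against the maxima over a
set of scenarios) is a *reporting* scale for radar charts and cross-scenario
tables, not a cluster metric. `kmeans_bundles()` runs Lloyd's algorithm,
best of `n_init` seeded starts, default `k = 6` to mirror the bundle count
used in reporting; the partition is invariant to column order and, through
z-scaling, to affine per-column rescaling.

Bundle membership is modelled by binomial logits on pairs of bundle labels.
The candidate design matrix combines site covariates with moving-window
landscape composition (circular 5 km buffer, ten cells; percentages are
computed by FFT convolution against the truncated buffer and sum to 100).
Predictors with variance inflation factor above 10 are removed iteratively
(largest first); the remaining predictors are standardized so coefficients
are standardized betas, and backward elimination drops whichever variable
most improves AIC until none does. Perfect separation is detected (deviance
collapsing to zero) and reported with the offending variable rather than
returned as a divergent fit. `lr_test()` gives `chi2 = 2 * delta-loglik`
against the chi-squared upper tail; `spatial_autocorrelation_check()` adds
standardized x- and y-coordinates to the final model and LR-tests the
difference. Adding x and y is a 2-df test; because a published variant of
this check reports 3 df without stating the third term, an `x:y`
interaction is available via `include_interaction = TRUE`, with 2 df as the
documented default.

On null data (membership generated from covariates alone) the coordinate
check stays non-significant at the nominal rate, and stepwise selection
retains a planted strong predictor essentially always. Note what AIC-based
backward selection does *not* promise: a pure-noise predictor survives
whenever its single-df deviance contribution exceeds 2, which happens with
probability about 0.157, so a model screening eight noise predictors keeps
at least one of them in roughly three runs out of four. That is a property
of the selection criterion, not of this implementation.

## Scenario orchestration and reporting

`run_scenario()` composes the layers (calibrating the annual demand if not
supplied); `run_scenarios()` shares the agent table, calibration and flow
graph across scenarios so differences are attributable to the scenario
settings alone. `compare_scenarios()` scales each service so the maximum
over all scenarios is exactly 100% and adds signed percent changes against
the baseline, flagging P export and sediment export as "lower is better".
A thin command-line wrapper (`inst/cli/srcscape.R`) exposes generate /
run-scenario / run-all / report over these functions.

## Numerical choices and problem sizes

* Price bounds default to [0, 2000] EUR/t; tolerance 1% relative per
  commodity; tatonnement damping 0.25 decaying as `1/(1 + iter/50)`.
* The reservation pick places the price a relative `1e-9` above the
  marginal agent's reservation so the marginal agent strictly prefers to
  enter (ties would otherwise resolve away from SRC).
* Priority-flood epsilon `1e-6` m; ASCII grids are written at 10
  significant digits, so round-trips are exact well beyond float32.
* The test suite exercises landscapes from 5x5 hand-built rasters to
  100x100 cells (the size at which market convergence and stability are
  verified exhaustively); the multi-seed property checks use ten 40x40 to
  60x60 landscapes, sizes at which every mechanism is already clearly
  expressed while the whole suite runs in about two minutes.

## Known limitations

* One aggregate annual commodity; no crop mix, rotation constraints or
  budget constraints (land, not capital, is the binding factor modelled).
* Euclidean transport distances; no road network.
* No adoption dynamics, social influence or farmer heterogeneity beyond
  site conditions — the model describes a mature commercial phase.
* The ESS parameter tables are class-level constants; within-class
  heterogeneity enters only through the raster inputs (R, K, slope).
* Synthetic landscapes support mechanism-level conclusions only; absolute
  service totals and coefficient values have no real-world referent.
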