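---
title: "Models and methods behind luces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind luces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luces)
```

`luces` simulates how alternative 2030 land-use pathways, crossed with
two emission-scenario climates, change four ecosystem services and the
relationships between them. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions taken
where the problem was genuinely open.

## 1. Demand: multi-objective programming and Markov projection

The decision vector is the six class areas x₁..x₆ (ha; cropland,
woodland, grassland, water, built-up, unused) plus population P
(10⁴ persons). Two linear objectives are maximized separately —
per-hectare ecological benefit (0.5, 2.72, 1.55, 16.12, −1.58, 0.08
million CNY/ha) for the ecological-protection scenario and per-hectare
economic benefit (12.88, 0.79, 7.74, 7.10, 785.85, 0.001) for the
economic-development scenario — under:

* total area fixed at 11,141,039.34 ha;
* 2127 ≤ P ≤ 3050 (policy carrying capacity);
* food security: P·10⁴·141.2·1.1411 ≤ x₁·4316.24·1.11·0.67, i.e. crop
  output (yield × multiple-cropping index × planted share) must cover
  per-capita demand at the 114.11 % self-sufficiency target. P is stored
  in 10⁴ persons and multiplied out to persons wherever a per-capita
  coefficient applies — otherwise the built-up constraint scale
  (hundreds of thousands of hectares) would be unreachable;
* per-class bounds: each policy baseline ± 1 % stored sorted as
  [lower, upper] (the published constraint listing prints two of the
  pairs in reversed order and truncates one digit; sorting plus the
  ± 1 % rule restores them unambiguously);
* P·10⁴·0.0109 ≤ x₅ (per-capita built-up land);
* ecological land x₂+x₃+x₄ ≥ 75 % of the total — a *lower* bound:
  protection policy guarantees at least that share, and the
  ecological-protection optimum is infeasible under the opposite sense.

The LP is solved exactly with the simplex method (`boot::simplex`),
after uniformly rescaling the system so right-hand sides are O(10³):
the solver's pivot tolerance is absolute and the raw problem spans
seven orders of magnitude. The returned vertex is re-verified against
every constraint at 10⁻⁶ relative tolerance, and binding constraints
are labelled so the optimum can be read structurally (the ecological
optimum is "woodland/grassland/water at their caps, built-up at its
floor"). Infeasible systems are diagnosed by a minimal total-violation
relaxation that names the conflicting constraints. There are no integer
variables; areas are continuous and reported at 2 decimals.

The natural-increase scenario instead projects the base-year areas one
decade through the row-stochastic form of the observed transition
matrix (`cross_tabulate()` + `markov_project()`). Total area is
conserved by construction; a class with no source area keeps an
identity row.

## 2. Allocation: expansion mining and the patch automaton

**Suitability (LEAS).** For each class k, cells that newly became k
between the two dated maps are positives; an equal-sized seeded draw of
other cells are negatives; a random-forest probability classifier
(`ranger`, 100 trees by default) on the driver rasters (elevation,
slope, climate, and any user-supplied surfaces) yields a per-cell
growth probability and driver importances. Classes with no expansion
are flagged static and get a zero surface — they can shrink but not
grow, which is the honest reading of "no evidence of growth".

**Automaton (CARS).** Each iteration, cells of surplus classes propose
one deficit class by roulette over suitability × neighbourhood
fraction × inertia, masked by the allowed-transition matrix (default:
everything permitted except water → unused). Cells with no neighbours
of the candidate class may convert only as random patch seeds where
suitability exceeds a threshold τ, which decays geometrically. Proposals
are accepted in weight-biased random order (exponential-keys weighted
sampling) capped by both the destination's remaining deficit and the
source's remaining surplus, so counts move monotonically toward demand
and can never overshoot. Inertia multiplies up for classes whose
deficit fails to shrink between iterations — the minimal rule that
makes demand-side pressure adaptive.

Defaults: 3×3 Moore window (border windows renormalized to their real
size), τ₀ = 0.5, decay δ = 0.9, seed weight 0.05 relative to a
same-class neighbour, 200-iteration cap, 0.1 % per-class demand
tolerance. None of the published results depend on these; they are
conventional values for patch-generating automata and all are
arguments. Validation metrics (overall accuracy and Cohen's kappa from
the 6×6 confusion matrix) are provided for comparing a simulated map
against an observed one.

## 3. Ecosystem-service models

* **Water yield** is the annual water balance Y = P − AET (mm), taken
  as printed rather than a Budyko-curve formulation because actual
  evapotranspiration arrives as an input raster. Yield is clamped at 0
  where AET > P: negative annual yield is physically meaningless.
* **Carbon stock** sums the four per-class pool densities (above,
  below, soil, dead; t/hm²) times an optional per-class climate
  multiplier (default 1 — the regional correction equations live
  outside this package and enter only through that hook). The default
  density table is **synthetic**: magnitudes plausible for subtropical
  south-west China, intended for generated landscapes.
* **Habitat quality** uses the half-saturation response
  Q = H·(1 − D^z/(D^z + k^z)). The response as printed in the source
  constraint listing (a minus sign in the denominator) is non-monotone
  and cannot be what the model family defines, so the canonical
  saturating form is implemented: Q = H at D = 0, Q = H/2 at D = k,
  strictly decreasing. Defaults z = 2.5 and k = half the observed
  maximum degradation, recomputed per run; both configurable.
  Degradation D sums, over threats (default sources: cropland and
  built-up land) and threat cells, the normalized weight × distance
  response × per-class sensitivity, with linear (1 − d/d_max) or
  truncated-exponential (e^(−2.99·d/d_max)) decay. It is computed by
  FFT convolution of the threat indicator with the radial kernel —
  exact for centre-to-centre distances, and verified in tests against
  an O(N²) pairwise oracle.
* **Soil retention** is RUSLE: A = R·K·LS·(1 − C·P), with per-class
  C and P lookups, erosivity from the annual power law R = a·P_mm^b
  (defaults a = 0.0668, b = 1.6266, a widely used fit for south-west
  China), and LS from the unit-stream-power form
  (A_s/22.13)^0.4 · (sin θ/0.0896)^1.3 with D8 flow accumulation.
  Flat terrain gives LS = 0, its minimal constant.

All four services are deterministic functions of their inputs.

## 4. Trade-off analysis

Service rasters are averaged over square sampling units (default 1 km,
rounded to a whole number of cells; units under 50 % valid are
dropped). Pairwise Spearman ρ is the Pearson correlation of average
ranks, with two-sided p from the t approximation; positive ρ reads as
synergy, negative as trade-off. No multiple-testing correction is
applied — six pairs are reported raw, matching standard practice in
this literature.

The spatial analysis is a geographically weighted regression: at every
unit, weighted least squares with an adaptive bisquare kernel (fixed
Gaussian and uniform kernels available), bandwidth chosen by
golden-section search on the corrected AIC. With an infinite bandwidth
the estimator reproduces global OLS exactly, which the tests use as an
oracle. The regression direction for a pair "A-B" is B on A by
convention (configurable); singular local designs are flagged and
their coefficients set missing. Local slopes are binned into
strong/weak synergy and trade-off at the median absolute slope, a
deliberately scale-free default.

## 5. The synthetic landscape generator

Terrain and all noise fields are spectral noise: white complex noise
filtered by (1 + (kL)²)^(−β/2) — flat below the cutoff 1/L, power-law
above — so the autocorrelation length L (default 8 cells) and roughness
β (default 3) are directly controllable and everything is seeded; one
master seed spawns a deterministic sub-stream per artifact. Climate is
mean + elevation lapse + north–south trend + noise, with the two
emission presets matching the study region's reported 2030 means
(851.55 mm / 16.55 °C moderate; 1080.60 mm / 16.47 °C high); actual
evapotranspiration is a clamped fraction field of precipitation, so
AET ≤ P cellwise by construction. Land use is built by rank-thresholding
driver-weighted latent fields (scarcest classes first), which realizes
the target fractions — defaults follow the study region's composition —
exactly up to rounding. The second-date map applies per-rule conversion
propensities at the cells where the destination's latent suitability
plus a neighbourhood-contagion bonus is highest, so the generating
ordering is known ground truth for the allocation stage to recover.

The default transition rules include both the dominant historical flows
(built-up expansion into cropland and woodland, cropland reclamation of
grassland, lake-margin water spread) and the smaller counter-flows that
decade-scale change in this region always shows (afforestation,
farmland-to-forest/grassland return, reclamation and degradation of
marginal land). The counter-flows matter structurally: they guarantee
every class some expansion over the period, without which a class the
demand stage asks to grow would have no learned suitability surface and
the automaton could not serve it — a situation real decade rasters do
not produce.

What the generator does **not** emulate: hydrologically consistent
drainage, real projection systems, anthropogenic spatial structure
(roads, planning boundaries), and multi-date climate trends. Passing
tests on these landscapes therefore demonstrate correctness of the
algorithms and their couplings, not calibration to any real region.

## 6. Numerical choices and problem sizes

* LP rescaling to O(10³), 10⁻⁶ relative feasibility verification.
* FFT convolution padded to the kernel radius; tiny negative round-off
  clipped to 0.
* The automaton's acceptance caps make per-class counts monotone in
  iterations; ties in the weighted ordering are broken by the seeded
  RNG, so runs are bit-reproducible under a fixed seed.
* Grid sizes used in the shipped tests: 48²–64² for property suites,
  256² for sampling-distribution checks, 512² for fraction convergence,
  200² for the end-to-end determinism run — sizes at which every suite
  completes in seconds while leaving the asymptotic behaviour visible.
* Reports serialize to JSON with unrounded doubles except where
  summaries are explicitly rounded; byte-identity of repeated runs is a
  tested invariant.

## Known limitations

* The LP reports a single vertex optimum; degenerate optima (the
  population column has zero objective weight in both scenarios) are
  resolved by the simplex pivot order, deterministically but
  arbitrarily.
* Static classes cannot grow in the automaton, by design; supply a
  suitability stack of your own if you need exogenous growth.
* The GWR is single-bandwidth; multiscale variants are out of scope.
* Carbon climate correction is a multiplier hook, not a model.
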