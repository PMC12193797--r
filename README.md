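# luces

Coupled land-use and climate scenario simulation of ecosystem services,
for landscape ecologists studying how alternative 2030 development
pathways reshape service supply and the trade-offs between services in a
plateau urban agglomeration.

The package chains four stages, each usable on its own:

1. **Demand** — how much of each land class in 2030? Either a Markov
   projection of the observed decade transition matrix (natural
   increase), or a linear program over the class areas
   x = (x1, …, x6) (cropland, woodland, grassland, water, built-up,
   unused; ha) and population P (10⁴ persons):

   - ecological protection: max f₁(x) = Σᵢ ESVᵢ·xᵢ
   - economic development: max f₂(x) = Σᵢ ECᵢ·xᵢ

   subject to a fixed total area Σxᵢ = S, population carrying capacity,
   food security (crop output ≥ per-capita demand × self-sufficiency),
   per-class policy bounds (baseline ± 1 %), per-capita built-up land,
   and ecological land (x₂+x₃+x₄) ≥ 75 % of S. Solved exactly by simplex.

2. **Allocation** — where does the demand land? A patch-generating
   cellular automaton: random forests learn per-class growth suitability
   from the cells that converted between two dated maps (the land
   expansion analysis strategy), then cells of surplus classes convert to
   deficit classes by roulette over suitability × neighbourhood effect ×
   adaptive inertia, with random patch seeding above a decaying
   threshold, until class counts hit demand.

3. **Ecosystem services** — four per-cell models: water yield
   Y = P − AET (mm); carbon stock as the four-pool class density
   (t/hm²); habitat quality Q = H·(1 − D^z/(D^z + k^z)) with D the
   distance-decayed, sensitivity-weighted exposure to threat classes; and
   RUSLE soil retention A = R·K·LS·(1 − C·P).

4. **Trade-offs** — grid-aggregated samples feed pairwise Spearman rank
   correlations (sign = synergy/trade-off) and a geographically weighted
   regression whose local slopes map where a pair trades off or
   cooperates.

A fully seeded synthetic-landscape generator (spectral-noise terrain,
elevation-lapsed climate under two emission scenarios, paired land-use
maps with a known transition process) makes every stage testable without
external rasters.

## Worked example

The ecological-protection demand optimum:

```r
library(luces)
solve_lp(build_lp("eps"))
#> <lp_result> EPS, optimal; objective 22837549.57 million CNY
#> <land_use_areas> (ha)
#>  cropland  woodland grassland     water   builtup    unused
#> 2126060.6 5522431.2 2979666.3  164919.0  332113.0   15849.3
#> population: 2127.00 x 10^4 persons
#> total: 11141039.34 ha
#> binding: total_area, woodland_upper, grassland_upper, water_upper,
#>          builtup_lower, unused_lower, population_lower
```

Reading: maximizing ecological benefit pushes woodland, grassland and
water to their policy upper bounds and built-up land to its lower bound;
cropland absorbs the remaining area. The binding labels say exactly
which constraints shape the optimum.

A full scenario on a 200×200 synthetic landscape (ecological-protection
land use × moderate-emission climate):

```r
rep <- run_scenario(scenario_spec("S3", seed = 42),
                    synthetic_config(shape = c(200L, 200L)))
rep
#> <run_report> S3 (EPS x RCP4.5), seed 42
#> demand (ha): cropland 2126060.65, woodland 5522431.16, grassland 2979666.28,
#>              water 164919, builtup 332112.95, unused 15849.3
#> ES means: wy 340.767, cs 135.903, hq 0.395, sr 4101.460
```

The report carries the per-service summaries and the 4×4 Spearman matrix
over ~1 km sampling units; `compare_scenarios()` lines several runs up
side by side, and `gwr_fit()`/`classify_relationship()` map where a
service pair is a local synergy or trade-off.

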