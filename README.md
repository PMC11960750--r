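# herdmap

Mapping where — and how intensely — grazing livestock are active, from the
low-frequency telemetry that virtual-fencing collars already record.

## Who this is for

Virtual-fencing systems (Nofence-class collars) log a GPS fix every ~15 min
while an animal is active (every 1–2 h while it rests), a cumulative
**activity index** per 30-min interval (a dimensionless count of
above-threshold heave-axis movements — a proxy for grazing intensity), and
collar temperature every 30 min. None of that reaches the end user as a
map. `herdmap` is for graziers, conservation land managers and movement
ecologists who want to turn those streams into utilization distributions,
grazing-intensity maps and range statistics without any additional
instrumentation.

## What it computes

* **Two utilization-distribution estimators** on a square grid (15 m cells
  by default):
  * *cell count* — dwell time per cell by the symmetric midpoint rule,
    with cumulative activity split equally among a sample's in-interval
    fixes, and contribution-weighted mean activity;
  * *Brownian Bridge Movement Model (BBMM)* — position density between
    fixes is a Brownian bridge with per-axis variance
    `σ²ₘ T α(1−α) + (1−α)²δ² + α²δ²`; σ²ₘ is fitted per animal by
    leave-one-out likelihood on alternating fixes, and an
    activity-weighted extension deposits `rate(t)·T/K` activity counts at
    each of `K` quadrature nodes, conserving total activity.
* **Core / full ranges** as 50% / 95% volume isopleths (highest-density
  cells accumulated to the mass level), with per-region summaries.
* **Bhattacharyya coefficient** `BC = Σᵢ √(Pᵢ Qᵢ)` between normalized
  distributions (0 = disjoint, 1 = identical).
* **Temporal analytics** — OLS validation of the activity index against
  observed grazing proportions, intensity thresholds (fitted, midpoint,
  and the 2,500 heuristic), bout extraction, hourly/fortnightly activity
  profiles, Spearman trend tests, and collar-vs-weather-station
  temperature comparison.
* **A seeded synthetic herd** (`simulate_herd()`) with per-minute ground
  truth (path + behavioural state), used by the whole test suite.
* **A CLI**: `run_herdmap()` / `exec/herdmap` with subcommands `simulate`,
  `ingest`, `map`, `ranges`, `compare`, `validate-grazing`, `profile`,
  `temperature`; every run writes a `manifest.json` with resolved
  parameters, input digests and the seed.

## Worked example

Three collared cows, 58 autumn days, all synthetic (seed 42):

```r
library(herdmap)

herd <- simulate_herd(sim_config(seed = 42))
obs  <- simulate_observations(herd)          # 8 days x 117 min per cow

## 1. does the activity index track observed grazing?
gp  <- grazing_proportions(obs, herd$activity)
fit <- fit_activity_grazing_line(gp)
fit
#> activity ~ grazing proportion: slope 3555.0, intercept 697.3,
#>   R^2 = 0.71, p = 1.69e-20, n = 72
round(threshold_from_fit(fit, 0.5))          # index at 50% time grazing
#> [1] 2475

## 2. space-use map and ranges
grid <- make_grid(herd$fixes, cell_size = 15, pad = 30)
occ  <- occupancy_cellcount(herd$fixes, grid)
p    <- normalize_raster(occ)
volume_isopleth(p, 0.50)
#> isopleth 50%: 21 cells, mass 0.5035, area 4725 m^2
volume_isopleth(p, 0.95)
#> isopleth 95%: 200 cells, mass 0.9505, area 45000 m^2

## 3. does activity concentrate where time is spent?
cum <- cumulative_activity_cellcount(herd$fixes, herd$activity, grid)
bhattacharyya_coefficient(p, normalize_raster(cum))
#> [1] 0.965
mean(classify_intensity(herd$activity)$samples$intensity == "high")
#> [1] 0.463
```

Reading the numbers: the validation line says a fully grazed half-hour
raises the index by ~3,600 counts over the ~700-count resting baseline
(R² = 0.71), so the index is a usable grazing-intensity proxy; the herd's
core range is 21 cells (~0.5 ha) against a 200-cell full range; space-use
and cumulative activity overlap at BC = 0.97 (cows are mostly active where
they spend time); and 46% of half-hours are high-intensity (index ≥ 2,500).

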