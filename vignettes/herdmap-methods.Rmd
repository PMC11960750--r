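---
title: "Mapping livestock space-use and grazing activity from collar telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping livestock space-use and grazing activity from collar telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Virtual-fencing collars record far more than a boundary alarm: a GPS fix
roughly every 15 minutes while an animal is active (dropping to one fix per
1–2 h while it rests), a cumulative *activity index* — a dimensionless count
of above-threshold heave-axis movements totalled per 30-minute interval —
and an instantaneous collar temperature every 30 minutes. `herdmap` turns
these three low-frequency streams into interpretable products for graziers
and ecologists: validated grazing-intensity proxies, utilization
distributions (UDs) over a square grid, core/full-range isopleths, and
overlap statistics between distributions.

## Data model and projection

All streams are parsed from a canonical long-format CSV into plain data
frames with UTC `POSIXct` timestamps. Coordinates are projected with a local
equirectangular projection about a user-supplied reference point,
`x = R cos(lat0) Δlon`, `y = R Δlat` (radians, `R = 6 371 000` m). For a
field a few hundred metres across the planar-versus-great-circle error is
below 0.5% at 500 m — orders of magnitude below the 15 m cell size — which
is why no projection database (UTM/PROJ) is needed. A warning is raised
beyond 1° of latitude from the reference, where the design envelope ends.

Duplicate `(animal, time)` records keep the first occurrence and log a
count: deterministic and auditable. Internally everything is UTC; analyses
that care about the clock (hour-of-day profiles, daily counts) accept a
timezone offset, because an autumn study in the UK spans the BST→GMT change
and the source material does not state which clock was used.

## The grid

Cells are half-open 15 m squares (`[o + iΔ, o + (i+1)Δ)`, 0-based indices),
so no boundary point is ever counted twice. The grid origin is snapped so
that the projected-space origin lies on a cell corner: grid placement is
then a function of the reference point alone, and results are reproducible
run-to-run regardless of which animal's data set the extent. Because the
original study's grid origin is unknowable, printed cell counts (e.g. a
75-cell core range) can shift by a few cells under a different origin; this
is an irreducible reproduction ambiguity, not a numerical defect.

## Cell-count utilization distributions

The cell-count estimator credits each fix with dwell time by the symmetric
midpoint rule: half of each adjacent inter-fix interval, each half capped at
`max_gap` (default 6 h, chosen so normal 1–2 h resting gaps are kept but
data dropouts do not fabricate dwell). The symmetric rule was chosen over
forward/backward crediting because it has no systematic directional bias;
the alternatives move a few cells' worth of mass at the study's sampling
rate.

Activity is allocated by splitting each 30-minute sample's count equally
among the fixes whose timestamps fall inside the interval (1–3 fixes at the
study cadence). This generalizes "split equally between consecutive
locations" and reduces to it exactly when two fixes bound the interval. A
sample with no interior fix goes whole to the nearest fix within `max_gap`,
else it is dropped and counted. Total credited time and total assigned
activity are conserved *exactly*, and the test suite asserts this.

*Average* activity is the contribution-weighted mean index per cell (a fix
receiving `1/k` of a sample carries weight `1/k`), keeping the units of a
30-minute index. Cells with no contribution are `NA` — empty, distinct from
an observed zero — and are excluded from normalization.

## The Brownian bridge estimator and its activity extension

Between consecutive fixes within `max_bridge_gap`, the path is modelled as
a Brownian bridge: at fraction `α` of a bridge of duration `T`, position is
isotropic normal with mean on the chord and per-axis variance
`σ²ₘ T α(1−α) + (1−α)²δ² + α²δ²`, where `δ` is the per-fix location error
SD (default 5 m, consumer GNSS; the collar vendor does not publish one).
Occupancy accumulates `T/K` seconds at each of `K = 100` midpoint
quadrature nodes (sub-1% discretization error at 15-minute bridges; the
suite checks K = 50 vs 200 agreement), with cell masses computed as
products of per-axis normal CDF differences — exact for the diagonal
covariance, unlike centre-density × area.

σ²ₘ is estimated per animal by the leave-one-out likelihood: every other
interior fix is predicted from the bridge spanning its neighbours. One
numerical point deserves emphasis: the likelihood variance must include the
left-out fix's **own** observation error `δ²` on top of the bridge
variance, because the residual contains `ε_i − (1−α)ε_{i−1} − αε_{i+1}`.
Omitting the `δ²` term (a formulation sometimes seen) inflates the estimate
by `1.5δ²/(Tα(1−α))` — about a factor of two at 15-minute spacing with
δ = 5 m. With the term included, the median estimate over 20 simulated
Brownian tracks (n = 200, dt = 900 s) recovers the truth within the
acceptance band of ±30%.

The activity-weighted extension defines, from each activity sample, a
constant rate `index / 1800 s` over its interval; each quadrature node at
absolute time `t` deposits `rate(t)·T/K` counts spread by its position
density. This construction was chosen among possible "stepwise" weightings
because it (a) reduces to the cell-count splitting rule in the point-mass
limit and (b) conserves total activity over bridge-covered time to
quadrature accuracy (asserted at 10⁻³ relative). Average activity is the
ratio of cumulative activity to occupancy expressed per 30-minute block,
masked below a 60 s occupancy floor where the ratio of two near-zero
densities would be noise.

One σ²ₘ per animal over the whole study is used (no behavioural
change-point variance): this matches the single-model usage being
reproduced; a dynamic BBMM is explicitly out of scope.

## Isopleths and distribution overlap

The core (50%) and full (95%) ranges are volume isopleths: cells ranked by
density, accumulated until the level is reached, ties broken
lexicographically by index for determinism. An exhaustive greedy oracle on
random 5×5 rasters verifies minimality, and nesting (50% ⊆ 95%) is a tested
property.

Distribution overlap uses the Bhattacharyya coefficient
`BC = Σᵢ √(Pᵢ Qᵢ)`. The radical form is the default even though the source
formula is sometimes printed without the square root, because only the
radical form satisfies the stated calibration — 1 for identical
distributions, 0 for disjoint support. `form = "product"` computes the
literal cross-product for sensitivity analysis.

## Temporal analytics

The activity index is validated against per-minute grazing/non-grazing
observation labels: each fully observed 30-minute period (coverage
threshold configurable, default 100%) yields a grazing proportion, and OLS
of index on proportion gives the validation line. Two thresholds are
derived: the fitted index at 50% grazing, and the midpoint between the
maximum exclusively-non-grazing and minimum exclusively-grazing indices,
rounded half away from zero (so 2 232.5 prints as 2 233). Intensity
classification uses `high ⟺ index ≥ threshold`: the source material writes
both strict and non-strict inequalities in different places; ≥ was adopted
so the two classes partition all values. Spearman correlations use average
ranks and the t approximation for p-values (standard at the study's n;
exact permutation would only matter below n ≈ 10).

## The synthetic herd: what it does and does not establish

`simulate_herd()` is first-class, tested code, not a fixture. It simulates
an alternating renewal behaviour process: grazing bouts with
gamma-distributed durations (mean 20.7 min — the observed mean bout length
used as a stated condition — shape 0.6, i.e. heavy-tailed), alternating
with non-grazing bouts (resting or short traveling) whose hourly mean
duration is set so the realized grazing time fraction follows a two-peak
diurnal profile (peaks 10:00/16:00, low overnight). Movement is
state-dependent: correlated slow wander while grazing, attractor-directed
walking while traveling (water trough in the NW corner), tight
mean-reverting jitter at hour-dependent rest sites, reflected at the field
rectangle (350 × 300 m). Fixes follow the active/resting cadence with 5 m
Gaussian error; activity counts are sums of per-minute gamma contributions
with state means 600/4200/2800 per 30 min (resting/grazing/traveling);
temperature follows a diurnal sinusoid (amplitude 4.4 °C, peak 13:30) plus
a decaying autumn trend fitted to the four printed fortnight means and a
cool band along the ridgeline. A single integer seed governs all streams;
identical seeds give byte-identical datasets.

On this stated world, without retuning: ~45% of activity samples are
high-intensity, the validation regression recovers R² ≥ 0.7 with the
half-grazing threshold between the state means, and cell-count and BBMM
occupancy maps agree at BC ≈ 0.91.

What a green test does *not* establish: the generator emulates the sampling
regime and state contrast, not cow cognition. Three known divergences from
the field data (documented, left as measured): exclusive-grazing 30-minute
periods are rarer than observed in the field, because an uncensored renewal
process with a 20.7-min mean bout interrupts most half-hours — real
observers ignored "minor pauses", lengthening label runs; observed mean
bout duration is biased slightly low by truncation at session boundaries;
and the average-activity surface separates more sharply from the cumulative
surface than in the field because synthetic rest sites are compact.

## Numerical choices, degenerate inputs, limitations

* Normalization requires positive total mass; all-zero rasters error.
* `NA` cells mean "no data" everywhere and are treated as zero mass in
  normalization and BC.
* A single fix contributes zero dwell; fewer than 3 fixes cannot support a
  σ²ₘ fit; an estimate at a search bound warns (e.g. a perfectly collinear
  noise-free track collapses to the lower bound).
* Bridge accumulation truncates the normal at ±6 SD (< 10⁻⁹ of mass,
  counted as leakage); off-grid leakage above 1% of bridged time warns that
  the grid is too small.
* Fortnight windows absorb trailing partial days into the final block (a
  58-day study has fortnights F1–F4, with days 57–58 in F4).
* Not implemented by design: dynamic/behavioural-switching BBMM,
  anisotropic location error, HMM/state-space smoothing, kernel-smoothed
  isopleth contours, satellite-imagery map rendering.
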