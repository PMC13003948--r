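---
title: "Methods: quantifying seabird–fishery spatial overlap from biologging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying seabird-fishery spatial overlap from biologging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Breeding Humboldt penguins (*Spheniscus humboldti*) are central-place
foragers: every foraging trip starts and ends at the nest, so during
chick-rearing the birds are confined to waters within a few tens of
kilometres of the colony. The same inshore waters support artisanal
purse-seine fleets targeting the penguins' main prey (anchoveta and other
small pelagics). Whether, where, and in which season the two space-use
patterns overlap is the core question for assessing indirect competition
and for marine spatial planning around breeding colonies.

`forageoverlap` implements the full analysis chain from raw biologging
records to overlap statistics:

1. **Dive detection** from 1 Hz depth traces.
2. **Dive–fix linking** through duty-cycled GPS positions and surface
   intervals.
3. **Trip segmentation and trip metrics** (duration, maximum and total
   distance, mean bearing).
4. **Hourly centroids** of dive-linked positions, the sampling unit for
   all spatial analyses.
5. **Kernel utilisation distributions** (KDE) with a two-stage plug-in
   bandwidth, 50/75/95% probability isopleths, land erasure, and
   geodesic areas.
6. **Overlap statistics**: isopleth intersection areas and the
   cross-type pair correlation function under two edge corrections.
7. **Seasonal mixed models** on log-transformed trip metrics.

Because no tracking or fishery data of this kind are openly deposited,
the package ships a first-class **synthetic-data generator** that
produces ground-truthed colonies with the statistical structure the
analysis assumes. Every pipeline stage is validated against that ground
truth.

## Dive detection and dive–fix linking

A dive is a maximal run of consecutive 1 Hz samples with depth ≥ 0.1 m
lasting ≥ 5 s; per-dive maximum and mean depth are computed over the run.
Both thresholds are arguments of `detect_dives()`. Two conservative
choices are fixed by design:

* **Gaps break runs.** `detect_dives()` refuses non-uniform series;
  `read_logger_csv()` splits traces at sampling gaps so a gap can never
  bridge a dive.
* **No zero-offset drift correction** is applied. Pressure-sensor drift
  handling varies by logger and deployment; the synthetic sensor model
  keeps surface readings within ±0.1 m of zero (Gaussian noise,
  sd 0.02 m), and users of real data can pre-process the depth vector
  before calling `detect_dives()`.

The non-diving time of a deployment is partitioned into *n* + 1 surface
intervals for *n* dives (`build_surface_intervals()`). Each dive is
assigned the temporally **last fix of the immediately preceding surface
interval** (`link_dives()`); dives whose preceding interval holds no fix
remain unlocated. Fixes timestamped inside a dive are physically
implausible (the antenna is under water) and are dropped with a warning.
Because loggers only acquire positions at the surface, every located dive
is a genuine at-sea position rather than an interpolated transit point —
the property that justifies treating located dives as foraging/searching
locations.

The depth-use summary (`depth_histogram()`, `depth_share()`) bins
**per-dive maximum depth** into half-open 5 m classes. Maximum depth is
the standard per-dive depth statistic in the diving literature; mean
depth is also carried on each dive event for users who prefer it.

## Trips, metrics, and hourly centroids

Positions within 100 m of the island shoreline are removed first
(`filter_nearshore()`): shoreline geometry and GPS jitter otherwise
produce spurious "at-sea" points on the colony.

`segment_trips()` splits each bird's located dives into trips at gaps
longer than 4 h (configurable). A stricter rule — require evidence of a
colony visit inside the gap — is not implementable on the located-dive
stream alone once near-shore fixes are removed, and with inter-trip
colony rests of many hours the two rules coincide; the gap threshold is
exposed as configuration. Trips shorter than 2 h, or with fewer than two
distinct fixes, are retained but flagged `excluded` with a reason, so the
exclusion bookkeeping is auditable.

The four trip metrics are: duration (start of first dive to end of last,
h), maximum geodesic distance from the nest (km), total distance (sum of
geodesic legs between consecutive located dives, km), and mean bearing
(circular mean — arctangent of mean sine and cosine — of nest-to-fix
initial bearings). All geodesic quantities are computed on the WGS84
ellipsoid via `geosphere`.

`hourly_centroids()` averages located dives per **bird × local calendar
date × hour of day**, in the local planar projection, and back-transforms
the mean. Calendar-hour binning (rather than pooling hours of day across
days) is deliberate: with ~20 birds, pooled hour-of-day binning could
never produce more than 24 centroids per bird, which is an order of
magnitude below the centroid counts multi-day deployments actually
support. Local time uses a fixed UTC−4 offset; timestamps are stored in
UTC throughout, and local clock time is used only for the daylight duty
cycle and hour binning.

## The local projection

All planar work (grids, centroids, point-process statistics) uses an
**ellipsoidal azimuthal-equidistant projection** centred on the colony:
a point at geodesic distance *d* and initial azimuth *a* from the centre
maps to (*d* sin *a*, *d* cos *a*), with forward and inverse built
directly on WGS84 geodesic routines. Radial distances from the colony are
exact by construction, and tangential (hence area) distortion is
*d*²/6*R*² < 2×10⁻⁵ at the 62 km analysis radius — far below every
tolerance in the pipeline. A transverse-Mercator variant on a sphere was
rejected: the sphere-vs-ellipsoid approximation alone costs ~0.3% in
distances at this latitude, dominating the projection error budget.

## Kernel utilisation distributions

The UD estimate is the standard bivariate Gaussian mixture
f(x) = n⁻¹ Σᵢ φ_H(x − xᵢ) evaluated exactly at the centres of a square
grid (cell 250 m by default) and renormalised over the grid; a grid that
captures less than 0.999 of the kernel mass is an error, not a warning.
Per-point contributions are truncated at 8 kernel standard deviations
(relative error < 10⁻¹⁴); `trunc_sd = Inf` gives fully exact sums, which
is how the engine is tested against a naive sum-of-Gaussians oracle at
10⁻¹².

### Plug-in bandwidth

`bw_plugin()` implements a two-stage unconstrained plug-in selector for
the bandwidth **matrix** (Wand–Jones family):

1. pre-sphere the data with the sample covariance;
2. compute sixth-order integrated density-derivative functionals ψ_r
   (|r| = 6) by double-sum estimation with scalar pilots derived from
   normal-reference eighth-order functionals;
3. use those to build AMSE-optimal pilots for the fourth-order
   functionals ψ_r (|r| = 4); functionals with an odd index component
   have no defined scalar pilot and borrow the geometric mean of their
   even neighbours;
4. minimise the asymptotic MISE,
   AMISE(H) = (4π)⁻¹ n⁻¹ |H|^(−1/2) + ¼ ∫ (tr H ∇²f)²,
   numerically over symmetric positive-definite H (Cholesky
   parameterisation, Nelder–Mead from the normal-scale start n^(−1/3) I
   on sphered data), and back-transform.

The selector is scale-equivariant by construction (selection happens on
sphered data), tracks the normal-scale rule on Gaussian samples, and
shrinks when the sample size grows — all properties the test suite
asserts. One bandwidth matrix is fitted per UD: the pooled penguin
centroids once, and each fishery season separately; nothing in the data
argues for sharing a bandwidth across such different point patterns.

### Isopleths, erasure, and areas

For probability level L, the density threshold t_L is the largest value
such that cells with density ≥ t_L hold at least mass L (cells sorted by
density; ties included — a deterministic, conservative rule). Isopleth
**areas are summed over member grid cells** (with the projection's area
correction, reported in km²); the marching-squares outlines
(`grDevices::contourLines` on a zero-padded grid, so all rings close)
are attached for GeoJSON export and plotting, with holes assigned by
even-odd containment.

Land erasure is a set-difference **on the same grid**: cells whose
centres fall in the named zones are removed, and both pre- and post-erase
areas are reported. Penguin UDs erase the island and mainland; fishery
UDs additionally erase the 1-nautical-mile (1852 m) coastal exclusion
band, where the regulated fleet may not set. Erasure happens **before**
area reporting and the remaining mass is *not* renormalised — the
contours themselves are unchanged by erasure. Running polygon
intersections on the shared density grid rather than on vector polygons
was a deliberate design choice: it makes erase, intersect, nesting and
area bookkeeping exactly consistent with each other (the same cells
answer every question), at a quantisation cost of one cell
(≈ 0.06 km² at 250 m) that is far below the reporting precision, and it
avoids fragile polygon boolean geometry. Isopleth nesting
(50% ⊆ 75% ⊆ 95%) holds cell-by-cell by construction.

`geodesic_area()` (WGS84 ellipsoidal polygon area, holes subtracted)
remains available for vector polygons, e.g. re-measuring exported
GeoJSON.

## Overlap statistics

`kde_overlap()` intersects post-erase cell masks of two isopleth sets on
the same grid: absolute overlap in km², and relative overlap as a
percentage of the penguin isopleth area. A planar sub-region ring
restricts the penguin side — used for the coastal-core sub-region along
the mainland beach, whose default delineation (a strip from the coast to
5.5 km offshore) is configuration, not dogma: any user-supplied ring
works, and its area is reported alongside.

### Cross-type pair correlation function

`cross_pcf()` estimates
g_ij(r) = Σ_{u∈i} Σ_{v∈j} e(u,v) κ_bw(r − ‖u−v‖) / (2πr λ_i λ_j |W|),
with λ = n/|W| and κ an Epanechnikov kernel. The default bandwidth is the
Stoyan rule 0.15/√λ_j. Two edge corrections are implemented:

* **Isotropic (Ripley)**: e(u,v) is the reciprocal of the fraction of
  the circle of radius ‖u−v‖ centred at u that lies inside the window,
  evaluated on a uniform angular grid (`n_angles`, default 512). The
  angular grid is part of the estimator's definition; the brute-force
  test oracle uses the same grid and agrees to 10⁻¹⁰.
* **Translation**: e(u,v) = |W| / |W ∩ (W + (v−u))|. Exact (closed form)
  for rectangular windows; for polygonal windows the set covariance is
  computed on the window's raster at its stated resolution.

The analysis window is the 62 km buffer minus land, rasterised at the
grid cell size. Distances are planar in the local projection (distortion
< 2×10⁻⁵, see above). g(r) = 1 indicates independence; the suite verifies
the CSR property (mean g within ±0.1 of 1 over 200 replicate pairs of
independent Poisson patterns), the oracle identity, and recovery of a
planted 100 m co-clustering scale. Simulation envelopes/significance
bands are out of scope.

## Seasonal mixed models

`fit_season_model()` fits log(response) ~ season + (1 | bird) by REML
with Satterthwaite degrees of freedom (`lmerTest`), returning the
spring-vs-autumn contrast, Wald 95% CI, p-value, variance components,
and a singular-fit flag. Singular fits (zero between-bird variance) are
reported, never errors: they indicate negligible between-individual
variation. With exactly one observation per bird the random intercept is
unidentifiable and the fit degrades to the season-only fixed-effect
model, flagged singular. Estimates are invariant to rescaling the
response (only the intercept moves under the log transform).

The per-trip "home range" response is defined as the 95% isopleth area of
a per-trip KDE of that trip's located dives (`trip_home_range()`, 100 m
cells, normal-scale fallback when the plug-in selector cannot run); this
definition is configuration, and the report table states medians/ranges
at either the per-trip or per-bird level (`summary_level`).

Validation is by simulation: under the null the test holds its size
(type-I error within [0.03, 0.07] at α = 0.05 over 500 replicates), and a
planted log-scale effect of 0.5 is recovered within ±0.05 with ~95% CI
coverage — the study-scale design (8 + 13 birds, each tracked in a single
season, ~3 trips each) is what the validator draws.

## The synthetic-data generator

`simulate_colony()` draws, per bird: a deployment window (1–8 days,
starting 08:00 local within the season's fieldwork window), alternating
foraging trips (lognormal durations, median 16 h) and colony rests
(median 18 h), a correlated-random-walk path that departs and returns to
the nest, and a dive schedule along the path. The generator's defaults
*are* the study conditions the pipeline targets:

* **8 autumn / 13 spring birds**, with 3 and 5 east-side nests
  respectively — the east/west nest-side split drives the bimodal
  space-use pattern: east-side (mainland-facing) birds head for the
  coastal strip; west-side birds forage offshore to the west/southwest
  but divert to the coastal strip with probability 0.35.
* **Depth mixture** with exactly 72.5% of dives drawn from the ≤ 30 m
  component (truncated gamma components above and below 30 m).
* **GPS duty cycle** of 60 s during the local day window (07:00–19:00)
  and 900 s at night, with per-surface-interval dropout
  P(no fix) = exp(−s/τ), τ = 120 s. The surface-interval distribution
  (lognormal, median 60 s, sdlog 1.0) was calibrated **analytically** —
  E[min(1, s/60) · (1 − e^(−s/τ))] ≈ 0.40 — so that roughly 40% of dives
  acquire a linked fix; the dive rate (21 h⁻¹) keeps dive bouts fully
  occupied so loafing pauses (whose long surfacings always acquire
  fixes) do not inflate that fraction.
* **Fishing sets** from a Thomas-type cluster process (Poisson parents,
  Gaussian offspring, rejection onto water inside the buffer and outside
  the 1-nm band), conditioned to 54 autumn sets on the inshore coastal
  strip (cluster sd 1.5 km) and 43 spring sets far south and offshore
  (sd 4 km). Unconditioned counts (`n = NA`) give the raw cluster
  process.
* **Stylised geometry**: a 3.01 km² elliptical island 6.5 km off a
  straight north–south mainland coast, a 1852 m exclusion band, a 62 km
  circular analysis buffer.

What the generator deliberately does **not** emulate: prey fields and
their environmental drivers (SST, chlorophyll), tides and currents,
sex/individual personality differences, device effects, or vessel
behaviour beyond clustered presence. Passing tests therefore demonstrate
that the *pipeline machinery* is correct and that the analysis recovers
the structure the generator plants (directional asymmetry, depth mixture,
fix-dropout rate, seasonal fishery contrast) — they do not validate
ecological conclusions about any real colony.

Bird counts are exposed as configuration rather than fixed: field sample
sizes of this kind are typically reported slightly differently across a
study's own tables, and nothing downstream depends on the exact count.

## Numerical choices and problem sizes

* Grid cell 250 m; analysis grid spans the 62 km buffer + 15 km margin
  (kernel-tail clearance for the dispersed spring fishery bandwidth).
  Halving the cell size moves isopleth areas by < 2% (tested).
* Threshold ties include all tied cells; contour tracing happens on a
  zero-padded grid so rings always close.
* Isotropic-correction angular grid: 512 angles (pipeline), part of the
  estimator definition.
* The full default colony (21 birds, ~13,000 dives, ~700 centroids,
  ~600×600 grid cells, 97 sets) runs end-to-end in under a minute; the
  test suite uses scaled-down colonies (5 birds, 1–2 days) everywhere
  except the end-to-end check, and the mixed-model validation uses 500
  replicates per property. These sizes are the package's chosen
  validation scale.

## Known limitations

* Erasure and overlap are grid-quantised (one 250 m cell ≈ 0.06 km²);
  vector-exact polygon clipping is intentionally not implemented.
* The isotropic edge correction is angular-grid-based, not the exact
  circle–polygon arc computation; at 512 angles the error is far below
  the estimator's sampling noise.
* The dive detector assumes a drift-free depth zero; apply your own
  drift correction upstream for real loggers that need it.
* The seasonal model treats season as a between-bird factor (no bird is
  tracked in both seasons, as in the motivating study design); with very
  few birds per season the random-intercept variance is weakly
  identified and singular fits are expected and flagged.
* `simulate_colony()` stores full 1 Hz traces in memory (~0.4 M samples
  per bird-day); a 21-bird colony needs a few hundred MB.
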