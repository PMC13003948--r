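# forageoverlap

Quantify spatio-temporal overlap between central-place-foraging seabirds
and purse-seine fisheries, from raw biologging records to overlap
statistics. The motivating system is breeding Humboldt penguins
(*Spheniscus humboldti*) tracked with archival GPS/depth loggers from an
island colony adjacent to an artisanal purse-seine fishing ground; the
pipeline is generic for any diving central-place forager whose
positions are acquired at the surface.

The package is for movement ecologists and fisheries scientists who need
a tested, reproducible implementation of this analysis chain:

- **Dive detection** — maximal runs of 1 Hz depth samples ≥ 0.1 m lasting
  ≥ 5 s, with per-dive max/mean depth (`detect_dives()`).
- **Dive–fix linking** — each dive receives the last GPS fix of the
  immediately preceding surface interval (`build_surface_intervals()`,
  `link_dives()`); fixes only exist at the surface, so located dives are
  true at-sea positions.
- **Trips and metrics** — gap-based trip segmentation; duration, maximum
  and cumulative geodesic distance, circular mean bearing
  (`segment_trips()`, `trip_metrics()`).
- **Hourly centroids** — located dives averaged per bird × date × hour in
  a local azimuthal-equidistant projection (`hourly_centroids()`).
- **Kernel utilisation distributions** — exact gridded Gaussian KDE with a
  two-stage unconstrained plug-in bandwidth matrix (Wand–Jones family,
  `bw_plugin()`); 50/75/95% probability isopleths with land /
  1-nautical-mile-zone erasure and km² areas (`kde_ud()`,
  `ud_isopleths()`, `erase_excluded()`).
- **Overlap statistics** — isopleth intersection areas, absolute and as a
  percentage of the seabird utilisation area (`kde_overlap()`), and the
  cross-type pair correlation function

  g_ij(r) = Σ_u Σ_v e(u,v) κ(r − ‖u−v‖) / (2πr λ_i λ_j |W|)

  under Ripley's isotropic and the translation edge corrections
  (`cross_pcf()`, `pcf_summary()`). g = 1 is spatial independence, g > 1
  clustering.
- **Seasonal mixed models** — log(response) ~ season + (1 | bird), REML
  with Satterthwaite p-values, singular fits flagged
  (`fit_season_model()`, `season_effects()`; broom-style `tidy()` /
  `glance()`).
- **Synthetic colonies** — a ground-truthed generator
  (`simulate_colony()`, `simulate_fishing_sets()`) reproducing the study
  conditions the pipeline targets: two seasons (8 + 13 birds), 1–8 day
  deployments, a 60 s day / 900 s night GPS duty cycle with
  surface-interval-dependent dropout calibrated to ~40% of dives
  acquiring a fix, 72.5% of dives ≤ 30 m, and seasonally contrasting
  clustered fishing-set patterns (54 inshore autumn, 43 southern spring).

## Worked example

Run the whole pipeline on the default synthetic colony:

```r
library(forageoverlap)
res <- run_overlap_pipeline(sim_config(), seed = 1)
#> simulated 21 birds, 13615 true dives, 65012 fixes, 97 fishing sets
#> detected 13615 dives, 40.5% with a linked fix
#> 5311 located dives after 100 m near-shore exclusion
#> 92 trips (18 excluded)
#> 675 hourly centroids
#> penguin UD: H trace 3.3 km2, 50% area 104.7 km2
#> overlap (50%): autumn 14.1%, spring 0.0%
#> seasonal models fitted for 5 responses
print(res)
#> <overlap_analysis>
#>   13615 dives (40.5% linked), 675 centroids, 92 trips
#>   dives <= 30 m: 72.8%
#>   50% overlap with autumn fishery: 14.7 km2 (14.1%)
#>   50% overlap with spring fishery: 0.0 km2 (0.0%)
```

Reading the numbers: 40.5% of detected dives carry a linked GPS fix
(brief surfacings defeat satellite acquisition, so commuting dives are
under-sampled); 72.8% of dives stay in the upper 30 m, squarely inside
the depth band purse seines fish. The pooled penguin utilisation
distribution and the two seasonal fishery distributions share one grid,
so the overlap report reads directly off it: in autumn the fishery's
core area sits on top of the penguins' coastal core (14.7 km², 14.1% of
the penguin 50% isopleth), while in spring the fleet moves south and the
50% areas do not intersect at all. The cross-PCF tells the same story as
a function of distance:

```r
res$pcf_summary
#> # A tibble: 4 × 7
#>   correction   peak_g peak_r has_peak r_above_min r_above_max season
#>   <chr>         <dbl>  <dbl> <lgl>          <dbl>       <dbl> <chr>
#> 1 isotropic   72.3       100 TRUE             100       10000 autumn
#> 2 translation 72.9       100 TRUE             100       10000 autumn
#> 3 isotropic    0.0359  10000 FALSE             NA          NA spring
#> 4 translation  0.0425  10000 FALSE             NA          NA spring
```

Autumn penguin centroids and fishing sets are strongly co-clustered at
short range (g ≫ 1, both edge corrections agreeing); spring shows no
association (g ≤ 1 everywhere). Seasonal mixed models on trip duration,
distance, home range and dive depths find no seasonal differences — as
expected, since the generator plants none:

```r
res$season_effects[, c("response", "estimate", "conf.low", "conf.high", "p.value")]
#> # A tibble: 5 × 5
#>   response       estimate conf.low conf.high p.value
#>   <chr>             <dbl>    <dbl>     <dbl>   <dbl>
#> 1 duration_h      -0.0176  -0.258     0.223    0.884
#> 2 total_dist_km   -0.0133  -0.189     0.162    0.881
#> 3 home_range_km2  -0.0373  -0.514     0.440    0.872
#> 4 mean_depth_m     0.0330  -0.0178    0.0839   0.200
#> 5 max_depth_m      0.0190  -0.0527    0.0908   0.599
```

`write_overlap_results(res, "out/")` writes the dive table, trip metrics,
centroids, isopleth GeoJSONs, overlap report, cross-PCF curves, and the
model table. `autoplot()` methods cover the UD raster, isopleth
outlines, PCF curves, and the depth histogram. A thin command-line
wrapper lives at `inst/scripts/forage-overlap.R`.

## Method documentation

The methods vignette (`vignettes/forageoverlap-methods.Rmd`) documents
the models and their assumptions, every tunable with units and defaults,
what the synthetic generator does and does not emulate, the numerical
choices (grid resolution, threshold ties, edge-correction
discretisation), and known limitations.
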