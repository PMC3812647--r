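# firescar

Burn-scar mapping from pre/post-fire multispectral image pairs, and
fire-regime analytics on the resulting catalogs.

After a wildfire, burnt surfaces drop sharply in near-infrared reflectance
and rise in middle-infrared. `firescar` turns that signal into GIS-ready
burn-scar polygons through a fixed-thresholding chain — the approach used
by operational national-scale burnt-area mapping services — and provides
the validation and regime statistics such services report. It is aimed at
remote-sensing analysts and fire ecologists who need a transparent,
scriptable, fully testable implementation of the whole chain.

The classification thresholds four biophysical indices,

    NBR        = (NIR − MIR) / (NIR + MIR)      (collapses after fire)
    NDVI       = (NIR − RED) / (NIR + RED)      (vegetation vigour)
    NDVI_MULTI = NDVI_pre − NDVI_post           (vegetation loss)
    ALBEDO     = (NIR + RED) / 2                (brightness / cloud proxy)

and fuses them (conjunctively) with a change/no-change mask from
radiometric change-vector analysis, after relative radiometric
normalisation and rule-based cloud/water/shadow masking. Post-processing
applies a 3×3 majority filter, removes objects under a 1 ha minimum
mapping unit, polygonizes connected components (unburnt enclaves become
"donut" holes), optionally aggregates nearby fragments into fire events,
and attributes each scar with its area and per-land-cover burnt hectares.

Validation follows the area-overlay protocol: detected / false / skipped
burnt area (DBA / FBA / SBA), detected-area efficiency `DBA/(DBA+SBA)`,
commission error `FBA/(DBA+FBA)`, omission error `SBA/(DBA+SBA)`, and the
producer's/user's accuracy complements. Catalog analytics cover the
fire-size distribution, the share of the largest events, the altitudinal
distribution of burnt area over a DEM, and the chi-square land-cover
fire-proneness test (observed burnt hectares per class against
expectation proportional to the class's landscape share).

A seedable synthetic-scene generator (`simulate_scene_pair()`,
`simulate_reference_pair()`, `simulate_terrain()`) produces fixtures with
known truth for every stage; it is first-class, tested code.

## Worked example

Simulate a 150×150 pixel scene pair at 30 m (a 4.5 km tile) with three
scars covering 10 % of the tile and light sensor noise, run the default
chain, and validate against the known truth:

```r
library(firescar)

sim <- simulate_scene_pair(geo_grid(150, 150, 30), burn_fraction = 0.1,
                           n_scars = 3, noise_sd = 0.01, seed = 42)
res <- run_pipeline(sim$pair$pre, sim$pair$post)
res$summary
#> # A tibble: 5 × 4
#>   stage         burnt_px burnt_ha n_polygons
#>   <chr>            <int>    <dbl>      <int>
#> 1 classify          1980     178.         NA
#> 2 median_filter     2206     199.         NA
#> 3 mmu               2206     199.         NA
#> 4 polygonize        2206     199.          3
#> 5 attribute         2206     199.          3

res$scars[, c("scar_id", "event_id", "area_ha")]
#> # Burn-scar catalog (3 scars, 3 events, 198.54 ha, CRS EPSG:32634)
#> # A tibble: 3 × 3
#>   scar_id event_id area_ha
#>     <int>    <int>   <dbl>
#> 1       1        1    66.2
#> 2       2        2    66.7
#> 3       3        3    65.7

accuracy_metrics(overlay_areas(res$scars, sim$truth$scars))
#> Burned-area accuracy report
#>   DBA 197.64 ha, FBA 0.90 ha, SBA 4.86 ha
#>   detected-area efficiency 97.60%
#>   commission error         0.45%
#>   omission error           2.40%
#>   producer's accuracy      97.60%
#>   user's accuracy          99.55%
```

The summary shows the classifier found 178 ha of burnt pixels, the
majority filter filled noise-induced holes up to 199 ha, nothing fell
under the 1 ha MMU, and three polygons were produced. Against the truth
polygons the map misses 2.4 % of the burnt area (noise pushes a few
burnt pixels past the index thresholds) and false-alarms on 0.45 % —
the map "detected-area efficiency" is 97.6 %.

The analytics work on any event catalog (here, hectares per event):

```r
fire_size_distribution(c(5, 50, 500, 5000, 50000))$n
#> [1] 1 1 1 0 2          # half-open classes: 5,000 ha falls in ">5,000"
largest_n_share(c(100, 300, 50, 800, 250), 2)$share
#> [1] 0.7333333
glance(landcover_proneness(c(shrub = 50, forest = 50),
                           c(shrub = 1000, forest = 9000)))
#>   statistic    df      p.value ...
#> 1     177.8     1     1.5e-40
```

Results have `tidy()` / `glance()` methods and `autoplot()` displays; a
command-line front end (`inst/cli/firescar`) exposes the
`run | validate | regime | simulate` subcommands for shell use.

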