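# rewildr

Spatially explicit monitoring of rewilding progress from wildlife
tracking and a habitat map.

## Who this is for

Rewilding (reintroduction) projects rarely have a fixed end state, which
makes "are we making progress?" hard to answer. What *can* be measured is
where each reintroduced population is, where it is predicted to thrive,
and how far the first has filled the second. `rewildr` turns a land-cover
raster and GPS occurrences of reintroduced animals into maps and area
tables of that gap, for conservation practitioners and movement
ecologists monitoring reintroduction sites.

## The method

For each species with tracking data:

* **Range (area of occupancy):** the 95% volume contour of a Gaussian
  kernel density over the pooled points of all individuals with more
  than 10 in-boundary observations. The contour is the smallest cell set
  holding 95% of the density mass.
* **Habitat selection:** a used/available design. One pseudo-absence per
  presence is sampled uniformly inside the study boundary but outside
  exclusion discs centred on every presence, each disc's area equal to
  the median individual range *A* (radius `sqrt(A / pi)`). For every
  point, the mean fractional cover of four habitats (broadleaf forest,
  free-standing trees, short grassland, tall grassland) within a buffer
  of that same area is the feature vector; a 500-tree random forest
  fits `P(presence | composition)` and is evaluated by stratified 5-fold
  cross-validated AUC.
* **Occupancy:** on the 30 m aggregated grid, cells with `P > 0.5`
  (strict) are *realized* occupancy inside the range and *potential*
  occupancy outside it.

Across species (S of them), each cell gets a **faunal complexity** count
(species with realized / potential occupancy, 0..S) and an **ecological
integrity** score: per species, an indicator that is 0 for unrealized
potential and 1 otherwise, averaged over species onto the lattice k/S.
Scoring with every range emptied gives the "before rewilding" baseline;
the difference maps where reintroductions have raised integrity.

A two-step land-cover mapping stage (fine-resolution neural pixel
classifier, then a coarse fractional-cover regressor trained on the
aggregated fine classification) is included for sites that start from
imagery rather than a finished habitat map, as are seeded synthetic
generators (`make_landscape()`, `simulate_tracking()`,
`synthetic_study()`) that plant known structure so the whole chain is
testable without any downloads.

## Worked example

```r
library(rewildr)

study <- synthetic_study(seed = 1)        # 6 x 6 km site, 2 tracked species
cfg <- pipeline_config(habitat = study$map, tracking = study$tracking,
                       boundary = study$boundary, seed = 1)
report <- run_pipeline(cfg)
print(report)
#> rewilding monitoring run: 2 species
#>                species realized_km2 realized_pct potential_km2 potential_pct
#> 1    forest specialist       1.3616         53.4        1.1888          46.6
#> 2 grassland generalist       1.5312          5.2       27.6656          94.8
#> high ecological integrity: 11.8% before, 19.8% after

report$integrity_tables$after
#>   label area_km2   percent
#> 1     0   0.0000   0.00000
#> 2   0.5  28.8544  80.15111
#> 3     1   7.1456  19.84889
#> 4 Total  36.0000 100.00000
```

Reading: the forest specialist has already filled 53.4% of the area
predicted to suit it (1.36 of 2.55 km²), while the generalist — whose
predicted area is the wide grassland plain — has filled 5.2%. Adding the
ranges lifted the share of the site at high ecological integrity (score
above 0.5) from 11.8% to 19.8%; the integrity table shows the full k/S
breakdown on the S = 2 lattice {0, 0.5, 1}. `render_report(report, dir)`
writes these tables as CSV plus the per-species probability surfaces,
occupancy rasters and range polygons.

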