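---
title: "Spatially explicit monitoring of rewilding progress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially explicit monitoring of rewilding progress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewildr)
```

## The monitoring problem

Trophic rewilding reintroduces locally extinct animals to restore
ecosystem processes. Reintroduction projects are typically open-ended, so
progress cannot be judged against a fixed end state; what can be measured
is how much of the *suitable* area each reintroduced population has come to
occupy, and how that occupancy accumulates across species into a
site-level picture. `rewildr` implements that measurement chain from two
inputs a project typically has: a land-cover classification of the site
and ranger- or collar-collected GPS occurrences of the reintroduced
animals.

The chain is:

1. **Species range** — the area of occupancy, estimated as the 95%
   volume contour of a Gaussian kernel density fitted to the pooled
   tracking points of all well-sampled individuals (more than 10
   in-boundary observations each; the bound is strict).
2. **Habitat selection** — a used/available design. Pseudo-absences are
   drawn uniformly inside the study boundary but outside exclusion discs
   centred on every presence point, one pseudo-absence per presence. The
   disc area equals the median individual range, absorbing the spatial
   sampling bias of ranger-collected points. Around every presence and
   pseudo-absence, the mean fractional cover of four modelled habitats
   (broadleaf forest, free-standing trees, short grassland, tall
   grassland) is extracted from a buffer disc of that same area, and a
   bagged-tree ensemble learns P(presence | composition).
3. **Occupancy** — the fitted probability surface on the 30 m aggregated
   grid is thresholded at 0.5 (strict): cells above the threshold inside
   the range are *realized* occupancy, above the threshold outside the
   range are *potential* occupancy, all others *not predicted*.
4. **Faunal complexity** — per-cell counts of species with realized and
   with potential occupancy, from 0 to the number of species S.
5. **Ecological integrity** — per species and cell an indicator that is 0
   only for unrealized potential (predicted but outside the range) and 1
   otherwise; the score is the mean over species, on the lattice k/S. A
   cell where no species is predicted scores 1: it already fulfils its
   rewilding potential. The "before rewilding" scenario treats every
   range as empty, so the same code path scores both scenarios and their
   difference maps where rewilding has raised integrity.

## Conventions that the numbers depend on

Small conventions move table-scale areas, so they are fixed and
documented:

* **One projected metric CRS.** All analysis happens in a single planar
  CRS in metres. Inputs in geographic (degree) coordinates are rejected,
  never silently reprojected — reprojecting a categorical raster would
  resample it.
* **Centre rule.** A cell belongs to a polygon (boundary or range) iff
  its centre does. The same rule drives range intersection, buffer
  extraction and area accounting, so the tables are mutually consistent.
* **Strict thresholds.** "More than 0.5" and "more than 10 observations"
  are strict inequalities; a cell at exactly 0.5 is not predicted, an
  individual with exactly 10 points is dropped.
* **NODATA discipline.** Unmappable cells (e.g. a fresh burn scar) are
  NODATA and leave both numerators and denominators of every percentage;
  buffer means skip NODATA cells rather than zero-filling them.
* **Argmax ties** in classification go to the lowest catalogue index;
  the catalogue order is fixed at creation and defines band order in
  every multi-band raster.

## Estimators and their defaults

**Kernel density and isopleth.** The KDE uses a product Gaussian kernel
evaluated at cell centres of a grid at the aggregated resolution (30 m by
default) padded by three bandwidths around the points, then renormalised
to unit mass on the grid. The default bandwidth is Scott's rule per axis,
\(h_j = s_j n^{-1/6}\); the bandwidth actually used is recorded on every
range estimate. The p% volume contour is the smallest cell set whose
cumulated mass reaches p — cells ranked by density — so the enclosed mass
lies in [p, p + one cell's mass]. On 10,000 points from an isotropic
Gaussian the 95% contour area is within a few percent of the closed form
\(\pi (2.448\,\sigma)^2\) (the tests assert 10%; the bandwidth inflates
the effective \(\sigma\) slightly).

**"Median species range."** The exclusion-disc and buffer area is the
median of per-individual 95% isopleth areas, each individual's KDE fitted
to its own points. The pooled-KDE area is reported alongside. This is the
reading under which a species with one wide-ranging individual does not
blow up everyone's buffers.

**Selection ensemble.** A 500-tree random forest with probability output
(vote fractions). Both resubstitution AUC and stratified 5-fold
cross-validated AUC are computed; the cross-validated value is the
headline, because resubstitution AUC of a flexible ensemble is near 1 by
construction. The AUC itself is the Mann–Whitney statistic computed from
midranks, identical to the all-pairs count with ties at one half.

**Land-cover models.** The two-step mapping (a fine-resolution pixel
classifier, then a coarse fractional-cover regressor trained on the
aggregated fine classification) uses single-hidden-layer feed-forward
networks with softmax output and weight-decay regularisation. Training
pixels are first balanced so that every class holds exactly the median
original class count — common classes sampled without replacement, rare
classes with replacement — then centred, scaled and split 80/20 with the
hold-out stratified by class. The `classifier_config()` object also
records architecture fields (layer count, dropout, batch size) for
backends that use them; the contract any backend must meet is softmax
output (probabilities summing to 1) plus the reported fit metrics
(accuracy and Cohen's kappa for the classifier, overall and per-class
r² for the regressor).

## The synthetic study

Because real imagery and telemetry cannot ship with the package, every
stage is exercised on seeded generators whose planted structure makes the
truth known:

* `make_landscape()` draws one Gaussian-smoothed white-noise field per
  class and labels each cell by the argmax of field plus per-class
  offsets, calibrated iteratively so realized cover matches the requested
  weights (within ±5 points on grids of 200+ cells a side). Weights can
  be zoned by latitude bands to emulate the common reserve layout of a
  heterogeneous mosaic adjoining a homogeneous grassland block.
* `simulate_tracking()` plants preference at the point-acceptance level:
  proposals from a Gaussian around each individual's centre are accepted
  with probability proportional to the preference weight of the habitat
  underfoot. Because no movement model intervenes, the true selection
  ratio is known exactly, giving clean parameter-recovery oracles.
  Individual centres scatter around the species centre with their own
  spread, decoupled from the within-range scatter, and an individual
  whose drawn centre has no reachable preferred habitat is re-settled —
  as real animals are.

`synthetic_study()` freezes the canonical conditions: a 6 × 6 km site on
a 300 × 300 grid of 20 m cells; a northern fifth of mosaic (35% broadleaf
forest, 15% free-standing trees, 30% short and 20% tall grassland) over
an otherwise near-pure tall-grassland plain, mirroring the ~70%
tall-grassland composition typical of the target reserves; correlation
length 250 m; a hard forest specialist (188 points, 9 individuals,
matching a pampas-deer-sized dataset) and a uniform-preference
generalist (120 points, 8 individuals) as a negative control.

Two properties of this design deserve flagging, because they are easy to
get wrong and generic to pseudo-absence methods, not artifacts of this
package:

* A *clustered* species with uniform preference still shows apparent
  habitat selection whenever the composition around its home ranges
  differs from site-wide availability, and random-fold cross-validation
  adds optimism because points from the same individual share buffers
  across folds. In the frozen design the generalist ranges in the
  homogeneous grassland, where buffer composition carries almost no
  spatial fingerprint, and its cross-validated AUC sits at 0.62–0.69
  across seeds — near, but measurably above, 0.5. Users applying the
  pipeline to real data should read modest AUCs in that light.
* What the generators do **not** emulate: GPS error, serially correlated
  relocations (movement), detection bias, seasonal range shifts, and
  classification error in the habitat map. Passing tests therefore
  certify the scoring algebra and the estimators, not robustness to
  those real-data pathologies.

## Numerical and degenerate-input choices

* KDE with all points identical and automatic bandwidth is an error
  (degenerate bandwidth); a single-axis degenerate spread borrows the
  other axis's bandwidth.
* Pseudo-absence rejection sampling is capped at 10^6 candidate draws;
  exhausting the cap raises "exclusion zone covers study area".
* Coarse aggregation marks a cell NODATA when more than half its fine
  cells are NODATA; trailing rows/columns that do not fill an
  aggregation block are dropped with a warning.
* Per-class r² is NA with a warning when a class's hold-out targets have
  zero variance.
* Integrity scores are validated against the exact k/S lattice; area
  tables bin by lattice value, not by ranges.
* Raster files are plain-text ESRI ASCII Grid bands plus a JSON sidecar
  (kind, catalogue, CRS, band order); integer rasters round-trip
  bit-exactly, floats to 10 significant digits.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the full chain on the
300 × 300 synthetic site (aggregated to 150 × 150), with 300-tree
ensembles and five seeds for the recovery checks — sizes chosen so the
whole suite completes in well under a minute on one core while leaving
every stage's statistical behaviour measurable. The pipeline defaults
(500 trees, 30 m cells) remain the recommended settings for real data.

## Known limitations

* Home-range estimation is a plain KDE; autocorrelation-aware estimators
  (aKDE, movement models) are out of scope, as are year-by-year range
  dynamics — all years are pooled.
* The integrity score covers the trophic-complexity dimension only;
  disturbance naturalness and connectivity are not quantified.
* Selection models use the four modelled habitat proportions as the only
  covariates; no detection-probability (imperfect detection) modelling.
* GeoJSON geometry handling covers simple polygons with holes; no
  topology repair beyond validity checking, and no on-the-fly
  reprojection.
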