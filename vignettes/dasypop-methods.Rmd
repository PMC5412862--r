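---
title: "Dasymetric population mapping with point-event densities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dasymetric population mapping with point-event densities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasypop)
```

## The estimation problem

Census counts live on administrative polygons; gridded applications need
them on pixels. The dasymetric approach taken here splits the problem in
two. A regression model, trained where counts are known, predicts
population *density* from ancillary covariates; that prediction, evaluated
per pixel, is only ever used as a *relative* weighting surface. The counts
themselves are then redistributed within each census unit proportionally
to the weights, so the output grid is exactly consistent with the input
census no matter how imperfect the model is. Model quality affects *where*
people are placed inside a unit, never *how many*.

The model is an unpruned random regression forest on census-unit log
density,

$$\log\left(\frac{N_i}{A_i}\right) \sim \bar{x}_{i1}, \dots, \bar{x}_{ip},$$

where $\bar{x}_{ij}$ is the mean of covariate $j$ over unit $i$'s pixels.
A forest is used for the same reasons it is standard in this literature:
it accommodates mixed continuous and binary covariates, non-linear
responses and interactions without specification, and its bootstrap
structure yields two free diagnostics — out-of-bag (OOB) error and
permutation importance. Both are computed by this package directly from
the ensemble's per-tree predictions and inbag counts rather than read off
a library summary: a unit's OOB prediction averages the trees that did not
sample it; variance explained is $1 - \mathrm{MSE}_{\mathrm{OOB}} /
\widehat{\mathrm{Var}}(y)$; and a covariate's importance is the increase
in OOB MSE after permuting its column and re-predicting. Owning these
computations makes their contracts directly testable (a constant covariate
has importance exactly 0; two fits with the same seed are identical).

The key structural assumption is cross-scale transfer: a relationship
fitted on unit-level *means* is applied to pixel-level covariate values.
Trees cannot extrapolate beyond the training range, so pixels more extreme
than any training unit are predicted at the range edge. This saturation is
inherent to the method and is the dominant error source at validation
scale (see *Limitations*).

## The two-arm experiment

`run_experiment()` runs the full analysis twice on the same region — once
with the covariate stack alone, once with the point-event density layer
(`twe`) added — and validates both maps against the finer census level
that training never sees. The comparison is reported as
(without − with), so positive differences mean the event covariate
improved the map. The event layer is informative precisely because events
are generated (and, in the real phenomenon, posted) by people: its density
carries information about the intensity noise that no static covariate
can explain.

## Event gridding choices

- "Rounded down" binning is floor toward $-\infty$ on both axes, not
  truncation toward zero. South of the equator the two differ by one cell,
  and truncation would merge the two cell rows straddling the equator.
- Cells are half-open, $[\mathrm{origin}, \mathrm{origin} + c)$: a point
  exactly on a cell's west or south edge belongs to that cell, so the
  lattice partitions the plane with no double assignment.
- The event lattice (default one tenth of the modelling cell) is anchored
  at integer multiples of its cell size, and its transfer onto the
  modelling grid assigns each source cell's count to the target cell
  containing the source cell's center — sum-preserving, so no event is
  lost or duplicated (asserted in tests). Refinement onto a finer grid
  uses nearest-value lookup. Nothing in the method requires the two
  lattices to share an origin.
- The covariate passed to the model is the raw per-cell count. No kernel
  smoothing is applied; the forest is free to learn any monotone
  relationship, and smoothing would add a bandwidth parameter with no
  basis for choosing it.

## Covariate stack choices

- Distance-to-class rasters are planar Euclidean distances between pixel
  centers, in degrees, computed with the exact two-pass parabolic distance
  transform; tests require exact agreement with a brute-force
  nearest-pixel search. Geodesic distances would be more faithful at
  continental scale but would break the exactness of the oracle; on a
  desk-scale region the difference is a near-constant factor that a tree
  model absorbs. This is a documented limitation, not an approximation
  silently applied.
- Nodata pixels neither anchor distances nor receive one: in an
  archipelago, sea pixels must not pull distance fields toward the coast
  of a masked area.
- Stack assembly orders layers lexicographically, making assembly
  deterministic regardless of argument order.

## Estimation and redistribution choices

- **Response transform.** Density is log-transformed by default
  (`transform = "log"`), matching the convention of the forest-based
  disaggregation literature; zero-density units are excluded from
  training because their log density is undefined, and the number
  excluded is recorded in the fit. `"identity"` is available for regions
  where zeros are meaningful and abundant.
- **Forest defaults.** 500 trees; `mtry` = one third of the covariates
  (the regression convention); minimum node size 5; trees unpruned. All
  exposed as arguments.
- **Pixel membership.** Each pixel belongs to exactly one admin unit
  (membership matrix); with polygonal input this corresponds to
  center-in-polygon with ties to the lowest unit id. Exact partition
  makes conservation exact.
- **Fallbacks.** A unit whose pixel weights sum to zero (e.g. fully
  nodata under the model) falls back to uniform allocation over its
  pixels; the count of such units is attached to the output. Units with
  zero valid pixels are an upstream error, not silently dropped here.
- **%RMSE denominator** is the mean observed count over exactly the units
  entering the comparison (after any drops), the only internally
  consistent choice when units can be dropped for having no valid pixels.

## What the synthetic generator emulates

`landscape_config()` defaults describe the study regime this package is
built to analyse, at desk scale:

| parameter | default | meaning |
|---|---|---|
| `grid_shape`, `cell_size` | 96 × 96, 0.01° | ~1.1 km pixels, ~11,400 km² region |
| `n_coarse_units` | 40 | training-level units (ASR ≈ 17 km) |
| `fine_per_coarse` | 12 | validation units per training unit (≈ 1:12, echoing national two-level census hierarchies) |
| `pop_total` | 10⁶ | persons; counts integerized by largest-remainder apportionment so totals are exact |
| `beta` | blt 0.8, lig 0.4, roa 0.15, ele 0 | log-linear covariate effects on standardized fields |
| `noise_sd` | 0.5 | sd of log-intensity noise ε |
| `tweet_rate` | 0.05 | events per person |
| `road_bias`, `snap_fraction` | 0 | bias dials, off by default |

Population intensity is $\lambda \propto \exp(\beta^\top z + \varepsilon)$
with pixel counts Poisson around it and rescaled to the exact total;
events are a Poisson point process thinned/placed proportionally to
population, with optional corridor bias and snapping of a fraction of
events to a small set of centroids (emulating coordinates quantized to
named neighborhoods). Admin units are lattice Voronoi cells of seeded
pixels, subdivided the same way, which guarantees contiguity, exact
partition and exact nesting.

Two generator-design points deserve emphasis:

- **Landscape scale.** The covariate random fields are smoothed with a
  correlation length of 1/8 of the grid side, so built patches span
  several coarse units. This mirrors settlement geography at census
  scale — towns are large relative to the administrative units that tile
  them — and it is a *requirement* of learnability: if landscape patches
  are much smaller than training units, unit covariate means homogenize
  toward the global mean and carry almost none of the pixel-level
  contrast the weighting layer must reproduce. (Diagnosed directly:
  with patches much smaller than units, fine-level %RMSE stays high even
  at zero intensity noise while oracle weights achieve ~0–2%.)
- **Effect magnitudes.** The default β give pixel log-density a standard
  deviation near 1 (density contrasts of roughly e^±2). Substantially
  heavier tails create isolated extreme hotspots that the unit-trained
  forest cannot represent (the saturation effect above), pushing
  fine-level %RMSE to 70–90% regardless of noise level. The defaults
  describe a moderate-density region in which the pipeline's recovery
  behaviour is informative rather than saturation-dominated.

What the generator does **not** emulate: temporal (diurnal/weekly) event
structure, demographic usage bias, true polygon boundaries (units are
pixel partitions; polygon export derives geometry from membership),
geodesic geometry, and landscape classes beyond the four synthetic layers.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative value of an event-density covariate under these conditions —
not that the same accuracy gains hold for any real country, period, or
social-media platform.

## Determinism and seeds

Every stochastic stage draws from a seed derived from the run seed and the
stage name (`derive_seed()`), so stages can be re-run independently and a
full run is reproducible byte-for-byte after serialization (numeric
formatting is fixed at `%.12g` in the ASCII-grid writer and `%.8f` in the
events writer). The forest uses a single compute thread; fits are
deterministic given table and seed.

## Problem sizes used in the test suite

Unit and property tests run on 32 × 32 regions with 6–14 coarse units and
forests of 50–300 trees; oracle-equivalence checks use up to 64 × 64
lattices and a few thousand events, where brute-force references are
instant. The end-to-end replication checks run the default 96 × 96
configuration with 500-tree forests over ten seeds, and the low-noise
recovery check summarizes five seeds by their median — single-seed %RMSE
under a heavy-ish-tailed synthetic density is variable, and the median is
the natural center for a skewed per-seed statistic.

## Limitations

- Cross-scale saturation: the forest cannot predict densities outside the
  training units' range, so extreme hotspots are systematically
  under-weighted. This bounds fine-level accuracy even with noise-free
  covariates and is the main reason validation %RMSE does not approach 0.
- Planar distances and areas (a fixed 111.32 km/degree) on an unprojected
  grid; adequate at desk scale, increasingly wrong toward the poles.
- The event covariate is treated as exogenous: feedback between mapped
  population and event collection, platform bias and coverage changes are
  out of scope. The bias dials (`road_bias`, `snap_fraction`) exist to
  probe robustness, not to model a specific platform.
- No covariate selection or hyperparameter search is performed; the full
  supplied stack enters the model.
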