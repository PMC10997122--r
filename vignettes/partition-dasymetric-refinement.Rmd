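---
title: "Partition-based dasymetric refinement: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-based dasymetric refinement: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popfine)
```

## The problem

Public gridded population surfaces place people on a regular grid, but
their resolution (typically 100 m or 1 km) is coarse relative to the
land-use fabric of a city, and within a cell the product's own weighting
has already smeared population across whatever the cell contains — water,
roads, fields, houses alike. `popfine` treats such a surface as the
*source of truth at its own resolution* and redistributes each cell's
population, first across land classes inside the cell, then down to a
nested finer grid. The census is never used to fit anything; it serves
only as the evaluation standard. This is the defining difference from
regression-based spatialization: the method needs no demographic
covariates, only the coarse surface and a land-use map.

## The model

Let cell *i* carry population $P_i$ and intersect land classes $j$ with
areas $A(i,j)$.

**Stratification.** Cells are partitioned into $k=3$ density levels by
natural breaks on the cell populations. A single city-wide weight model
would average away the fact that, say, water near a dense waterfront
carries some population in the source data while water in rural wetlands
carries none; fitting the class weights *within density strata* keeps that
heterogeneity. Since the source grid is equal-area, raw cell counts and
densities give identical partitions, so counts are used directly.

**Weights.** The per-cell area fraction
$D_{mij} = WA(i,j) = A(i,j) / \sum_j A(i,j)$ plays two roles. Averaged
over the cells of stratum $m$ it yields the stratum land-class weight

$$D_{mj} = \frac{\sum_{i \in m} D_{mij}}{\sum_{i\in m}\sum_j D_{mij}},$$

whose denominator equals the number of fragment-bearing cells of the
stratum because each cell's fractions sum to one — the implementation
computes both forms and refuses to continue if they disagree. Per cell,
the two constraints combine multiplicatively and renormalize:

$$f(i,j) = D_{mj}\, WA(i,j), \qquad
  F(i,j) = \frac{f(i,j)}{\sum_j f(i,j)}, \qquad
  P(i,j) = P_i\, F(i,j).$$

The normalizer $\sum_j f(i,j)$ is provably positive for any cell with
fragments (each present class contributed its own fraction to $D_{mj}$,
so $D_{mj}>0$ there); this too is asserted, not assumed. A consequence
worth knowing: with a single stratum of identically composed cells,
$F(i,j) \propto WA(i,j)^2$ — the dual constraint *sharpens* the area
weight rather than reproducing it, and the test suite pins this algebra
down on a fixture.

**Downscaling.** Each fine cell $I$ nested in parent $i$ receives

$$P_I = \sum_j P(i,j)\,\frac{A(I,j)}{A(i,j)},$$

which conserves every parent total whenever the children's class areas sum
to the parent's. A fine cell mapped entirely as water is then zeroed and
its mass moved to its siblings in proportion to their pre-rule
populations. We read "the population is summarized into the parent cell"
as *within-parent redistribution* — the only reading that preserves the
dasymetric conservation guarantee; returning the mass to a report, the
main alternative reading, would silently deflate city totals. A parent
whose children are *all* water yet which carries population cannot satisfy
both the zero rule and conservation; conservation wins, the rule is
skipped there, and the parent is flagged in the diagnostics.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `k` | 3 | strata | low/medium/high; any $k \ge 2$ works if the data have that many distinct values |
| `factor` | 4 | — | 100 m → 25 m; any integer ≥ 2, one level per run |
| `sliver_tol` | 1e-6 | fraction of cell area | overlay fragments below it are dropped and logged |
| `water_classes` | `"water"` | — | classes subject to the zeroing rule |
| taxonomy | 12 first-level classes | — | fully configurable |

The fine overlay scales the sliver fraction by `factor^2` so that the
*absolute* area threshold matches the coarse one; a fine fragment that
survives therefore always has a surviving coarse counterpart
$A(i,j) > 0$, and the downscale formula can never divide by a dropped
denominator.

## Numerical and degenerate-input choices

- **Natural breaks** are computed by exact dynamic programming on the
  sorted values ($O(kn^2)$ with vectorized inner loops), minimizing total
  within-class squared deviation. Ties are broken toward the
  lexicographically smallest break vector via a greedy left-to-right
  reconstruction against suffix-optimal costs. Class intervals are
  upper-closed (a value equal to a break falls in the lower class), the
  common GIS convention. When the cell populations have fewer distinct
  values than $k$ (an all-zero raster, say), `jenks_breaks()` errors but
  the orchestrated pipeline degrades to a single stratum — the weights are
  then unpartitioned but everything downstream still runs and conserves.
- **Geometry** is computed by the package itself: cells are axis-aligned
  rectangles, so parcel–cell intersection is a Sutherland–Hodgman clip
  (exact for a convex window), and overlapping same-class parcels are
  unioned by an exact vertical-slab sweep before areas are summed.
  Overlaps *between* classes are a hard error: the weighting model assumes
  the land-use map partitions space, and double-counted area would bias
  $D_{mj}$ invisibly. Shared boundaries in a clean mosaic never trigger
  the (more expensive) union path, which only runs where bounding boxes
  strictly overlap.
- **Unrefined cells** (no land-use coverage at all) keep their population
  and fall back to an equal split over their children: conservation over
  invented structure. Their count and mass appear in the run report.
- **Nodata** raster cells are dropped, not zeroed — in WorldPop-style
  products nodata means "not land", while a genuine zero is a populated
  area with nobody in it and legitimately joins the low stratum.
- The reported **SD** is the population standard deviation of the
  estimates (divisor $N$, Taylor-diagram convention), **%RMSE** is RMSE
  divided by the mean census count in percent, and **R²** is
  $1-\sum(Y_a-X_a)^2/\sum(Y_a-\bar Y)^2$, which may be negative.
  The SD is of the estimates, not of the errors.

## What the synthetic generator emulates — and what it does not

`generate_scenario()` builds a rectangle-mosaic landscape by recursive
random splits (areas are exact and the counting oracle is cheap — the
reason rectangles were chosen over, say, Voronoi cells), assigns each
class a true density per fine cell, and derives *truth* fine populations,
the coarse raster (exact per-parent sums of truth) and the census (exact
per-unit sums) from one seed. Multiplicative lognormal noise with mean 1
(`noise_sigma`, default 0 for exact tests, 0.2 where statistical
behaviour is wanted) perturbs truth without biasing totals. Admin
boundaries are snapped to fine-cell edges so each fine cell belongs to
exactly one unit.

What this does **not** emulate: curved parcel boundaries and topology
errors of real cadastral data, the spatial autocorrelation of real
population beyond what the mosaic induces, misregistration between
layers, and the upstream product's own model error. Passing tests
therefore certify the *arithmetic and the conservation guarantees* of the
method, and the recovery comparisons certify its behaviour *under the
model's own assumptions* (class densities roughly constant within a
stratum). They do not certify accuracy on any real city; that depends on
how well a land-use map predicts residential density there.

Default scenario sizes — 50×50 coarse cells at factor 4 (40 000 fine
cells) for the conservation run, 30×30 for the recovery comparison — keep
a full suite run in seconds while still exercising thousands of
mixed-class cells; results were indistinguishable in kind on larger grids.

## Design decisions that were genuinely open

- **File formats.** Rasters travel as ESRI ASCII grids with a `.prj`
  sidecar carrying the CRS identifier, printed at 17 significant digits so
  round trips are bit-exact; vectors as GeoJSON (legacy-style `crs`
  member). Both are plain text, diffable and self-contained, which suits
  a pipeline whose audit trail is CSV throughout.
- **No reprojection, ever.** Readers verify that all layers share one
  projected metre-unit CRS and reject geographic CRSs by identifier.
  Silent reprojection changes areas, and areas are the entire signal here.
- **Admin apportionment** splits straddling cells by intersected area
  rather than assigning by centroid; centroid rules break conservation
  exactly at the unit boundaries where evaluation happens.
- **Stratum weights are city-wide**, not per administrative region: the
  stratification is already the spatial-heterogeneity control, and
  per-region weights would starve sparse strata of cells.
- **Water keeps its (small) stratum weight at the coarse stage**; zeroing
  happens only at the fine stage, where "entirely water" is decidable.
  Excluding water from $D_{mj}$ as well would double-penalize mixed
  waterfront cells.
- An optional largest-remainder **integerizer** exists for census-style
  outputs but is off by default; the model is defined on reals.

## Known limitations

- Overlapping *different-class* parcels abort the run rather than being
  resolved by priority; land-use maps that genuinely overlay uses need
  dissolving upstream.
- One refinement level per run (100→25 m), no cascades.
- No smoothing across neighbouring coarse cells: a sharp population edge
  in the source survives refinement. Handling neighbour consistency is a
  known open problem for this family of methods.
- Self-intersection screening of input rings is quadratic and skipped
  above 200 vertices per ring.
- `%RMSE` requires a strictly positive mean census count, and metrics
  need at least two units.
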