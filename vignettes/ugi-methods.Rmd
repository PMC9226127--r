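---
title: "Methods: MSPA, CA-Markov and circuit-theory connectivity for urban green infrastructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSPA, CA-Markov and circuit-theory connectivity for urban green infrastructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugimorph)
```

`ugimorph` studies urban green infrastructure (UGI) — the network of
forest, cropland, grassland and water inside and around a city — as it
appears in categorical land-cover rasters. This vignette is the
package's account of the science: the models, their assumptions, the
parameters that matter, and the numerical choices behind them.

## Spatial frame and raster conventions

Every raster lives on a `grid_frame`: `n_rows x n_cols` square cells of
`cell_size` metres, row 1 northernmost, cell (r, c) centred at
`(origin_x + (c - 0.5) h, origin_y - (r - 0.5) h)`. All stages require
frame-identical inputs (`check_frames()` names the first differing
field). Cell counts become areas exactly once, in `cell_area_km2()`;
every public area is in km². Nodata cells follow one global rule: they
act as background for MSPA geometry and as barriers for connectivity,
and are excluded from every area, transfer, and kappa denominator.

Files are plain-text ESRI ASCII grids
(`NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/NODATA_VALUE`), which
round-trip integer rasters bit-exactly. The package deliberately reads
and writes only this format: it is self-describing, diffable, and
sufficient for single-band categorical work; reprojection, multi-band
imagery and compressed container formats are out of scope.

## MSPA segmentation

`classify_mspa()` partitions the green foreground into seven structural
classes on the 8-neighbour lattice with edge width `s` (cells,
default 1):

1. **Core** — foreground whose Chebyshev distance to the nearest
   background cell exceeds `s`; with `s = 1` this is one 3x3 erosion.
   Chebyshev is the natural metric for an 8-neighbourhood analysis;
   the raster border is treated as background (the world outside the
   study area is not habitat), which prevents spurious border cores.
   Both choices are exposed as arguments.
2. **Islet** — every cell of an 8-connected foreground component that
   contains no core: isolated stepping-stone patches.
3. **Edge / perforation** — non-core, non-islet foreground within `s`
   of its own component's core. The cell is *perforation* when its
   nearest background is a hole — a 4-connected background component
   not touching the raster border (4-connectivity for background is the
   digital-topology dual of 8-connected foreground) — and *edge*
   otherwise. Ties (hole and open background equally near) resolve to
   edge: the outer boundary function dominates.
4. **Bridge / loop / branch** — the remaining foreground forms
   8-connected connector components. A component touching two or more
   distinct core components is a *bridge* (inter-core corridor); one
   core component through two or more disjoint contact zones is a
   *loop* (intra-core corridor); anything else is a *branch*. A contact
   zone is an 8-connected run of the component's cells within Chebyshev
   distance `s + 1` of core — with `s = 1`, exactly the connector cells
   separated from core by the one-cell boundary band.

Connector labeling is at the component level. Pixel-level MSPA
implementations may split a single connector into bridge and branch
parts; this divergence is deliberate (component-level labels are the
unit corridors are reasoned about) and recorded in the map metadata.

The classification is verified cell-for-cell against an independent
brute-force implementation of the same rules (per-cell distance scans,
hand-rolled flood fills) on hundreds of random small landscapes, and by
structural properties: the seven classes exactly partition the
foreground, core shrinks monotonically with `s`, and class areas are
invariant under whole-map translation.

`major_cores()` keeps 8-connected core components above a strict area
threshold — 10 km² by default, the conventional cut for patches large
enough to act as stable ecological sources. On synthetic frames a few
kilometres wide that default excludes everything; tests and the
pipeline config scale it to the frame.

## Change-rate indices, barycenters, kappa

For a class with start/end areas `U_a`, `U_b` over `T` years, the
single change rate is `P_s = (U_b - U_a)/U_a * 1/T * 100%` (decline
negative, undefined at `U_a = 0` — an error, not infinity). The
comprehensive rate aggregates all transfers:
`P_c = sum_i dU_i / (2 sum_i U_i) * 1/T * 100%`, where `dU_i` is the
area leaving class *i* (cross-tabulation row sum minus diagonal). The
factor 2 halves the double count of each moved cell, bounding `P_c` to
`[0, 100/T]`. Transfer-out and transfer-in interpretations give the
same total, so the choice is observationally neutral. `T` is the
difference in calendar years between the labeled dates; fractional
values are allowed.

The barycenter of a class is the area-weighted mean of its patches'
geometric centroids (`X_t = sum C_i X_i / sum C_i`); on a uniform grid
this equals the mean of member-cell centres, which is how
`migration_track()` computes it. Coordinates are projected map metres —
reprojection to geographic coordinates is left to the user.

Cohen's kappa over jointly valid cells is
`(p_o - p_e) / (1 - p_e)` with `p_e` from the two maps' marginal class
frequencies. Two identical constant maps give `p_e = 1`; the package
returns 1 with a warning, by convention. The implementation is
cross-checked in the tests against `e1071::classAgreement`. Agreement
bands follow the usual convention: 0.60–0.80 "high", 0.80–1.00 "very
high".

## CA-Markov prediction

`ca_markov(map_t1, map_t2, interval_years)` estimates
`P_ij = n_ij / sum_j n_ij` from the cross-tabulation; classes absent at
the first date get identity rows and are flagged. Demand projection is
the matrix power: `areas_target = areas_now %*% P^n`. The number of
steps is `round(horizon / interval)` — annualizing the matrix by roots
is *not* attempted (matrix roots of stochastic matrices are non-unique
and can have negative entries), so the prediction horizon should be a
whole number of calibration intervals.

Scenario constraints (`scenario_spec()`):

- **frozen classes** — identity transition rows and immovable cells
  (economic priority freezes construction land);
- **protected mask + classes** — inside the mask, listed classes never
  convert (ecological priority protects forest, water and cropland
  inside an ecological red line). Restriction is a hard freeze, not a
  soft penalty, matching red-line policy semantics;
- **row multipliers** — off-diagonal outflow scaled then the row
  renormalized (economic priority boosts unused-land outflow, default
  factor 1.5 — the canonical value is not established, so it is a
  config parameter);
- **terrain rules** — step functions over slope or elevation bands
  multiplying per-class suitability by a factor in [0, 1]. Slope comes
  from the DEM by central differences (one-sided at borders), in
  degrees. Step bands are used because no functional form for terrain
  influence is established.

Suitability of converting a cell to class *k* is the fraction of *k* in
the 5x5 window (the conventional CA contiguity filter; window size is
an argument) times terrain and protection factors, clipped to [0, 1].

The allocator (`allocate_ca()`) splits each growing class's net demand
evenly over `n_iterations` (default 10) with largest-remainder
rounding, so per-iteration quotas sum exactly to demand. Each
iteration, eligible donor cells — valid, not frozen, not protected,
with positive transition probability toward the target, and belonging
to a class that itself has surplus — are ranked by
`suitability x P(current -> target)` plus a seeded jitter of magnitude
1e-12 (far below any meaningful score difference) for deterministic,
unbiased tie-breaking; the top-ranked convert. The donor-surplus
condition keeps every class within one cell-area of its demand when
constraints do not bind; binding constraints produce a logged
shortfall, never an exception. Total landscape area is conserved
exactly, and identical inputs plus seed give a bit-identical predicted
raster.

Hold-out validation imitates practice: fit on dates 1–2, predict
date 3, compare with the observed date 3 by kappa and per-class
producer/user agreement.

## Circuit-theory connectivity

A resistance surface maps each land-cover class to a per-cell movement
cost. The package defaults (forest 1, water 2, grass 3, cultivated 5,
unused 50, construction 100) encode the usual ordering — green classes
cheap, built land near-impassable — but resistance values are study
decisions: they are the first argument of every connectivity function
and are recorded in each output.

*Least-cost corridors*: on the 8-neighbour lattice, traversing a link
costs the mean of the two cell resistances times the centre distance
(diagonals x sqrt(2)). Core-to-core paths use zero-cost virtual
terminals tied to every cell of each core, giving the true multi-source
shortest path (Dijkstra via `igraph`). Unreachable pairs are reported
as disconnected with infinite cost. Optimality is verified against
exhaustive enumeration of simple paths on small grids.

*Pinch points*: each passable cell is a node with conductance `1/R`;
neighbouring nodes are joined by the harmonic mean of their
conductances — the series combination of two half-cells — with
diagonal links scaled by `1/sqrt(2)` to compensate path-length
distortion (a 4-neighbour graph is available by flag). All cells of
core A merge into a source supernode injecting unit current, core B
into ground; voltages solve the sparse graph Laplacian system (direct
sparse solve via `Matrix`; the grids this package targets stay well
below the size where an iterative solver would pay off). Node current
is half the sum of absolute incident link currents — so a series cell
carries exactly the through-current — except at the merged terminals,
which report the full injected current. Effective resistance is the
source voltage per unit injected current. Terminals in different graph
components are detected up front and reported as infinite resistance
with zero current. Solutions satisfy Kirchhoff balance to solver
precision and match dense reference solves to 1e-8 in the tests;
Rayleigh monotonicity (raising any resistance never lowers effective
resistance) is spot-checked.

## The synthetic landscape generator

No public multi-date classified rasters accompany this kind of study,
so the generator is a first-class module that produces series with the
statistical structure the analysis assumes:

- **Contagion.** Each class gets an independent Gaussian-smoothed noise
  field (bandwidth = `contagion`, in cells); a cell takes the class
  with the largest field value plus a per-class offset, calibrated
  iteratively (60 rounds of proportional feedback, stopping at 0.5
  percentage points) so realized class shares track the request. Larger
  contagion gives larger, smoother patches with the core/edge/connector
  structure MSPA expects.
- **Known transitions.** Between consecutive dates, each source class's
  cells are reassigned so the count moving to each target matches the
  recipe's transition matrix via largest-remainder quotas; *which*
  cells move is decided by local target-class density (5x5), so change
  is spatially clustered. Quota-based assignment was chosen over
  per-cell probability perturbation deliberately: adding a neighborhood
  bonus to per-cell transition probabilities biases the realized
  marginal rates away from the nominal matrix, whereas quotas keep the
  empirical cross-tabulation within rounding of it — which is what
  makes parameter-recovery testing meaningful.
- **DEM and masks.** Smooth relief = optional planar trend (e.g. high
  northwest, low southeast) plus a low-pass random field; policy masks
  threshold a smoothed field at the coverage quantile, giving a few
  compact blobs.

Every output is a pure function of `(recipe, seed)`; each operation
draws from its own stream derived from the seed and the operation name,
so adding one generator call never perturbs another's output.

What the generator does *not* emulate: classification error and mixed
pixels, anisotropic urban growth along road networks, multi-scale patch
hierarchies, and realistic class adjacency preferences (rivers between
specific classes, altitude-zoned vegetation). Passing tests therefore
demonstrate correctness of the algorithms and recoverability of known
parameters under idealized spatial structure — not that the models
describe any particular city.

## Problem sizes and test design

The test-suite sizes are chosen so the statistical checks are sharp but
the whole suite stays interactive: oracle equivalence on landscapes up
to 15x15 (hundreds of seeds), transition recovery on 300x300 pairs
(tolerance 0.03 per entry), hold-out validation on 200x200 three-date
series (kappa at least 0.60, the "high" band), circuit solves against
dense references on 6x6 grids (1e-8), and full-pipeline byte-level
reproducibility on 60x60 three-date runs. The acceptance script uses a
120x120 pipeline and 300x300 recovery pairs for the same reason.

## Known limitations

- Component-level connector labels (above) differ from pixel-level
  MSPA tools near complex connector geometries.
- The allocator converts the globally top-scoring cells per class; it
  does not trade off between competing growth classes beyond the
  donor-surplus rule, so under tight joint constraints the shortfall
  log should be inspected.
- Prediction horizons that are not whole multiples of the calibration
  interval are rounded to the nearest whole number of Markov steps.
- Barycenters and corridors are reported in projected frame
  coordinates; no geodesy is performed.
- Whether water joins the MSPA foreground while staying cheap in the
  resistance surface is a study decision; both memberships are
  arguments (`to_foreground()` codes, resistance lookup) rather than
  package policy.
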