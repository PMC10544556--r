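---
title: "Space use and dyadic interactions with time-local convex hulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space use and dyadic interactions with time-local convex hulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dyadhulls` analyses satellite-telemetry trajectories of territorial
central-place foragers — animals, such as denning foxes, whose movements are
anchored to a fixed site. This vignette is the package's account of the
methods: the models and their assumptions, every tunable parameter with its
default and rationale, the numerical choices, what the synthetic-data
generator does and does not emulate, and the known limitations.

## Data model and projection

A trajectory is one animal-season of fixes `(t, lon, lat)` at roughly 1.5–2 h
intervals. All geometry runs in planar metres: fixes are projected with a
spherical transverse Mercator centred on the data (mean Earth radius
6 371 008.8 m). Over a study window under 200 km this agrees with geodesic
distances to about 0.2% (the tests check 1% against an independent geodesic
oracle) and is exactly invertible, which is all that hull areas and
boundary distances require. All animals of a study must share one projection
centre; `project_to_plane()` applied to the list of trajectories guarantees
that.

Exact duplicate `(id, t)` rows are collapsed; the same timestamp with
different coordinates is an error rather than an average, because a collar
emits one fix per schedule slot, so conflicting rows indicate corruption.
Fixes with missing coordinates are dropped and reported. Timestamps are UTC
only.

`v_max`, the scaling constant of the time-scaled distance, is the maximum
displacement/interval ratio over consecutive fixes with `Δt ≥ 300 s`; the
floor matches the collars' location-timing jitter and stops near-zero
intervals from inflating the maximum.

## Screening

**Residency.** The empirical variogram bins half squared displacements by
time lag. Range residents plateau; dispersers grow. The verdict compares the
mean semivariance in a *tail* window (default 25–40 days, long enough that a
seasonal range would have decorrelated) with a *plateau* window (default
5–10 days), declaring residency when `tail ≤ 1.5 × plateau`. The field
practice this automates is a visual judgement, so the windows and the 50%
tolerance are configuration with stated defaults rather than constants.

**Range shifts.** `detect_range_shift()` scans all splits for the one
minimizing total within-segment squared distance to the segment centroids
and declares a shift when the centroid separation exceeds the larger segment
RMS radius. This is deliberately a least-squares heuristic, not a fitted
movement model. Under slow mean reversion it is liberal — transient drift in
a strongly autocorrelated track can trip it — so it is a screening aid whose
flags deserve inspection, and the downstream remedy (drop the short period
before the shift) is the analyst's call.

**Excursions.** Foraging excursions are qualitatively different from
within-range movement and would inflate hull-based ranges. Distances to the
track centroid are transformed along the Tukey ladder of powers, with the
exponent chosen on the grid `λ ∈ [−5, 5]` (step 0.025) that maximizes the
Shapiro–Wilk W of the transformed sample (samples above 5 000 values are
thinned deterministically by quantile to the test's limit). The filter is
one-sided,

    upper bound = median(transformed d) + 3 × MAD(transformed d),

with the *unscaled* MAD — no 1.4826 consistency constant — because the rule
is literally "3 median absolute deviations". Distances near zero are
legitimate den attendance, so no lower bound is applied. A degenerate MAD of
0 collapses the bound to the median and flags every larger value; the
safety net is an error when more than half the fixes are flagged, which
signals a non-resident input rather than excursions. Maximal runs of flagged
fixes become excursion segments, and the kept trajectory is re-centroided
once (a single pass; iterating moved nothing in practice while complicating
the contract).

## Time-local convex hulls

Each fix is the parent of a local convex hull built from its nearest
neighbours under the time-scaled distance

    TSD_ij = sqrt(Δx² + Δy² + (s · v_max · Δt)²).

`s` weighs time against space: at `s = 0` hulls are purely spatial; as `s`
grows, simultaneous-but-distant points separate. `suggest_s()` returns the
balance point at which the median time term equals the median spatial term
for fix pairs about one period of interest apart (12 h by default, matching
a ~9–10 h position autocorrelation at 12–16 fixes/day), clamped to
`[0.001, 1]`. This is a documented surrogate for the visual diagnostic used
in the field; on schedule-typical simulated tracks it lands in 0.01–0.2.

Neighbours use the adaptive *a*-method: points are taken in order of TSD
while their cumulative TSD stays within `a`. At least two neighbours are
always retained, since a hull needs three points. `suggest_a()` gives a
neutral default (the median cumulative TSD of the 15 nearest neighbours);
`a_diagnostic()` exposes the curve — 95%-isopleth coverage and area versus
`a` — that an analyst uses to balance excluding used areas against including
unused ones. The choice is inherently visual and is not automated.

Per hull the package counts **all** trajectory fixes enclosed,
boundary-inclusive (a parent on its own hull edge must count), and derives
the time-use metrics with the 12-h inter-visit gap: enclosed fixes are
partitioned into visits wherever the gap since the previous enclosed fix
reaches the IVG; NSV is the number of visits and MNLV the mean fixes per
visit. (The enclosed-point count could alternatively be restricted to
nearest neighbours only; counting all enclosed fixes is the package's
reading, chosen because the isopleths are meant to grade *use density*.)
Fixes whose neighbour set is degenerate (e.g. repeated den coordinates)
yield no hull and are reported; more than 20% of them is an error.

**Isopleths.** Hulls are sorted by a metric — enclosed-fix density, NSV or
MNLV — in descending order, ties broken by smaller area then earlier parent
time so results are deterministic, and their union is accumulated until the
fraction of unique fixes enclosed reaches each level (a fix inside several
hulls counts once). 95% is the home range, 50% the core. Because levels
share one ordering, lower levels are prefixes of higher ones: nesting is
structural, and the tests verify it spatially too.

## Overlap and Minta coefficients

Neighbours are animals whose 95%-isopleth boundaries lie within 3.2 km (a
red-fox home-range radius; configurable). Static overlap is
`sqrt((A∩B/A)·(A∩B/B))`, the geometric mean of the two directed fractions —
symmetric, 0 for disjoint and 1 for coincident ranges.

Within the shared area (the intersection of the two home ranges), use is
scored at simultaneous fixes: greedy one-to-one matching in time order
within a 5-min buffer, greedy so drifting schedules cannot double-pair. The
spatial coefficient for animal A with areal share `q = shared/range`,
`k` fixes inside the shared zone and `m` elsewhere in the range, is
`L = ln[(k/(n·q)) / (m/(n·(1−q)))]`, tested with an exact two-sided binomial
test of `k` in `k+m` at probability `q`. The temporal coefficient takes the
four joint presence/absence cells, expected probabilities as products of
each animal's own marginal frequency among the pairs (the independence
null), `odds_c = n_c/(n·p_c)` and

    L_ixn = ln[(odds_AB + odds_00) / (odds_A0 + odds_0B)].

Zero cells produce zero odds and, where a denominator vanishes, infinite
sentinels — never silent drops or continuity corrections, so reconstructed
values stay comparable with published tables that print raw zeros.

Two p-values are offered for `L_ixn`. The default is the chi-square
goodness-of-fit with 1 df (four cells, two estimated margins). Fix series
are serially autocorrelated, however — position autocorrelation of ~9.4 h
against 1.5–2 h fixes — which makes the chi-square anticonservative. The
robust option (`p_method = "rotation"`) is a circular time-rotation null:
margins are invariant under rotation, so every cell is a function of the
simultaneous count alone and all `n` circular shifts of B's presence series
are evaluated at once through an FFT cross-correlation. Rotation preserves
each series' autocorrelation and calibrates the test (the suite verifies a
≤7% significant rate over 500 independent-regime simulations).

Labels follow sign and significance: attraction/avoidance (spatial) or
simultaneous/solitary (temporal) at `p < 0.05`; dyads are symmetric (both
significant, same sign), asymmetric (opposite signs), singular (one), or
random. A non-significant temporal result with `|L_ixn| ≥ 0.25` is reported
as a "trend": published dyad tables label `|L_ixn| ≈ 0.1` random but
`≈ 0.45` a trend, so a magnitude cutoff exists in practice; 0.25 sits
between the two and is exposed as `trend_threshold`.

## Habitat composition

Rasters are integer grids (ESRI ASCII on disk) with a legend;
reclassification maps original ids onto analysis classes (e.g. seven
tundra-coast classes: barren, wetland, tundra, shrubland, forest,
intertidal, sea ice) and refuses unmapped ids by name. Composition uses the
cell-centre rule — a cell counts if its centre lies inside the region —
which is deterministic and resolution-documented; halving the cell size
moves proportions by under 5% on smooth fixtures. Water and infrastructure
classes are handled as an exclusion set over which proportions are *not*
computed, with the excluded fraction reported. The package emits the long
analysis-ready table (animal × ordering × class) for multivariate
comparisons; the comparisons themselves (MANOVA and relatives) are standard
library statistics and are out of scope here.

## The synthetic generator

The generator provides data with exactly the structure the analysis
assumes, so every stage is testable without downloads.

* **Movement**: a discrete mean-reverting walk,
  `next = current + attraction·(den − current) + noise`, started from its
  stationary distribution. Defaults: 90 days at 1.5–2 h intervals (12–16
  fixes/day, the collar schedule), `attraction = 0.1` per step and
  `step_sd = 350 m`, giving a stationary axis sd near 800 m and a 95% range
  radius near 2 km — fox-like for coastal tundra. The variogram plateaus by
  construction.
* **Excursions**: chosen runs are displaced along a random bearing with a
  half-sine profile scaled to `[0.5, 1] × multiplier ×` the 95% range
  radius. The floor at half the peak makes *every* excursion fix distant,
  so recovery can demand the whole run is flagged, not just its apex.
* **Dyads**: dens are separated by 1.5 × the theoretical 95% radius so the
  ranges share a lens-shaped area; both animals run the same schedule with
  ±2-min jitter. Regimes manipulate the schedule, not the dynamics, so the
  temporal truth is unambiguous: *cohesive* relocates B next to A (with
  compliance 0.9) whenever A is in the shared area; *exclusive* reflects
  B's fix through its own den whenever both are inside simultaneously;
  *independent* does nothing.
* **Habitat**: a nucleation-and-growth mosaic — class nuclei in numbers
  proportional to the configured shares, cells taking the nearest nucleus's
  class — yields contiguous patches whose realized shares track the target.

All randomness flows from one seed through a documented splitting scheme
(`derive_seed`, a fixed affine map mod 2³¹−1), so outputs are byte-identical
per seed. What the generator does **not** emulate: GPS measurement error,
landscape-coupled movement, memory or Lévy-type foraging, and
behaviourally-driven heterogeneity in fix schedules. Passing tests therefore
demonstrate that the estimators recover known structure under the stated
movement model — not that field data meet those assumptions.

## Numerical choices

* Hull polygons are exact (convex hulls of neighbour sets; shoelace areas;
  boundary-inclusive membership with a size-scaled tolerance). On ≤12-point
  toys the areas equal an independent gift-wrapping oracle exactly.
* Unions of hundreds of hulls are non-convex, so isopleth areas, shared-area
  sizes and boundary rings are computed on a regular grid of cell centres
  (default 256 cells along the larger extent, i.e. a relative area error on
  the order of perimeter × cell size). Point-in-isopleth membership — which
  drives fix counts and Minta cells — is always tested exactly against the
  member hulls, never against the grid. Boundary distances between
  isopleths use exact convex-polygon pair distances.
* The permutation t-test draws subsets from the *sorted* pooled sample, so
  swapping the groups reproduces the identical p under the same seed, and
  uses the add-one convention `p = (1 + #{|t*| ≥ |t|})/(n_perm + 1)`.
* Wilcoxon and Fisher tests delegate to the standard exact/approximate
  machinery (`wilcox.test`, `fisher.test`), which already implements the
  small-sample exact nulls and tie corrections; the package contributes the
  result container and seed discipline.

The test-suite runs everything at deliberately moderate problem sizes —
20–60-day tracks, 100–500 replicate seeds — which characterize the
estimators well while keeping the default suite quick; all sizes are
ordinary function arguments, so heavier runs are one parameter away.

## Known limitations

* The range-shift check is a heuristic with a liberal false-alarm rate on
  strongly autocorrelated resident tracks; treat flags as prompts, not
  verdicts, and detect a single shift only.
* Isopleth areas inherit grid resolution; at the default grid a very
  filamentous range is slightly smoothed. Increase `grid_n` where area
  precision matters.
* Raster I/O is ESRI ASCII only, with nearest-neighbour alignment and no
  reprojection.
* The chi-square temporal p is anticonservative under schedule
  autocorrelation — that is why the rotation null exists; prefer it when
  fix intervals are short relative to position autocorrelation.
* `s` and `a` selection are diagnostics, not optimizers: per-animal values
  chosen visually in the original workflow cannot be recovered exactly, and
  the defaults aim to be sensible rather than identical.
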