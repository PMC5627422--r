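---
title: "Building and validating a mapping table between misaligned aggregated databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating a mapping table between misaligned aggregated databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealink)
```

## The method

Two aggregated databases — a medical one keyed by `Spatial_Id_Medical` and
an ecological one keyed by `Spatial_Id_Eco` — are made interoperable in two
steps.

**Step 1: construction.** A chain of transition matrices
$M_1, \dots, M_p$ ($p \ge 1$) links the ecological ID system (level 1)
through temporary IDs to the medical one (level $p+1$). Each matrix is a
plain set of (source, target) ID links; within a matrix, the connected
components of the bipartite link graph fall into four mutually exclusive
cardinality patterns (one-to-one, many-to-one, one-to-many, many-to-many).
Composing the chain gives the eco–medical linkage: an eco and a medical ID
are linked iff a path runs through all $p$ matrices. The direction of the
relationship is always from fine to coarse: the database with the larger
median unit area seeds the analysis units, because the reverse direction
would require disaggregation and hence spatial estimation error —
the one thing the method exists to avoid.

The central construction is the **overlap merge**. After composition, any
set of medical units connected through shared ecological units (transitively
closed) is collapsed into a single analysis unit. This makes the
eco → analysis assignment a total function: every ecological unit belongs to
exactly one analysis unit, so every variable can be aggregated upward with
no value ever split. When no overlaps exist, analysis units coincide with
medical units. A fine unit split across intermediate codes needs no special
handling: if its codes reconverge to one medical unit, composition yields a
single link; if they diverge, the overlap merge fires. Dangling IDs
(present on one side of a matrix junction, absent on the other) are dropped
from the linkage but always reported — real crosswalks have gaps, and
silent loss would corrupt the validation totals.

**Step 2: validation.** Three independent checks:

1. *Common variable.* A variable present in both databases (births in the
   motivating application) is sum-aggregated to the analysis scale on both
   sides and compared per unit by the relative difference
   $r_i = 100\,(e_i - m_i)/m_i$, with the medical count as denominator.
   Units with $m_i = 0$ are excluded and counted. We report the median and
   IQR of both signed and absolute differences, since a systematic
   undercount shows up as a location shift of the signed distribution.
2. *Spatial continuity.* Member geometries are dissolved per analysis unit;
   a unit is fragmented when its dissolved territory has more than one
   connected part. Fragmented units are hazardous downstream because their
   centroid — how aggregated data are usually georeferenced — can fall
   outside the unit; the package counts those cases too.
3. *Spatial resolution.* The decline index is the ratio of the median unit
   size (area in km², or population) at a target scale to that at the
   finest initial scale. Comparing the analysis scale's index with those of
   coarser administrative reference units shows how much resolution the
   merge actually cost.

## Design choices

* **Analysis IDs** are the sorted member medical IDs joined with `+`
  (`m007+m012`). Deterministic, traceable, and stable under row order.
* **Contiguity is rook-style**: two parts count as connected only when they
  share a boundary segment of positive length. A corner touch is a
  fragment — one cannot travel between two parts through a zero-width
  junction without leaving the unit. The snap tolerance for shared-boundary
  tests is $10^{-9}$ coordinate units, absorbing floating-point slivers
  from the dissolve.
* **Centroid** means the area-weighted geometric centroid of the
  (multi)polygon, holes subtracted; a centroid exactly on the boundary
  counts as contained.
* **Quartiles** use linear interpolation between order statistics (type 7,
  R's default); the reported IQR depends on this choice, so it is fixed and
  documented. The median of an even number of member values is the midpoint
  of the central pair.
* **Direction ties** (equal median areas) are an error asking for an
  explicit base rather than an arbitrary coin flip.
* **Missing values** stay missing. They are excluded from mean/median/
  weighted-mean aggregation; a sum over a unit with missing members is
  computed over the present ones but flagged incomplete. Nothing is imputed
  as zero, because undercounting is exactly what the validation step must
  be able to see.
* **Degenerate inputs**: empty matrices, blank IDs, duplicate unit IDs,
  negative counts, out-of-range proportions, zero-area geometries and
  zero-weight weighted means are all hard errors naming the offending unit
  or line; IDs are opaque strings throughout (leading zeros in commune and
  zip codes survive).

Geometries are handled with planar primitives written for this package
(shoelace areas, even–odd point-in-polygon, boundary-cancellation dissolve):
inputs are assumed to be in a projected planar CRS with km units, and areas
are planar km². The dissolve splits all boundary edges at vertices lying on
them, cancels segments that appear an even number of times (internal
borders), and stitches the remainder into rings; it is exact for geometries
whose shared borders are collinear — grids and administrative tilings —
and members that merely touch at corners deliberately stay separate parts.

## The synthetic test bed

`generate_geography()` builds a three-level geography on a square grid of
1 km cells: region-growing assigns cells to intermediate codes and codes to
medical units, so every non-planted unit is edge-connected by construction
and the planted structure is unambiguous ground truth. The parameters, with
defaults chosen to mirror the shape of a national commune/zip/discharge-zone
hierarchy at desk scale:

| parameter | default | meaning |
|---|---|---|
| `grid_n` | 20 | fine cells per side (400 cells of 1 km²) |
| `n_codes` | 70 | intermediate codes |
| `n_medical` | 60 | coarse medical units (≈ 6.7 cells each, matching the commune-to-zone ratio of the motivating application) |
| `frac_one_to_one` | 0.05 | codes frozen at a single cell (the ~5% of zip codes that coincide with one commune) |
| `frac_split` | 0.01 | cells linked to a second code inside the same medical unit (the <1% of large communes split across zips, which reconverge) |
| `overlap_rate` | 0.02 | medical units sharing a cell with a neighbour, planted in adjacent pairs (the <1% overlap situation that forces merges) |
| `fragmentation_rate` | 0.02 | medical units given one distant cell (the ~2% discontinuous units observed nationally) |
| `lambda_count` | 30 | Poisson mean of events per cell |
| `undercount` | 0.06 | probability an event is missing from the medical database |
| `seed` | 1 | drives all generator randomness |

Counts are paired by **binomial thinning**: the medical database records,
per unit, the sum of its cells' true Poisson counts each thinned with keep
probability $1-u$. Thinning keeps counts integral and non-negative and has
a closed-form calibration target: the per-unit relative difference has
expectation close to $100\,u/(1-u)$ (for $u = 0.06$, 6.38%; the per-unit
ratio carries a small positive Jensen bias of order $u/S$ for a unit total
$S$). Each cell's events are counted once, in the medical unit of its
primary code, so with $u = 0$ the pipeline recovers zero difference in
every unit exactly.

What the generator does *not* emulate: realistic unit shapes and size
distributions (cells are unit squares; real communes span three orders of
magnitude in area), spatially correlated event rates, boundary changes over
time, and crosswalk errors other than dangling IDs. Passing tests therefore
demonstrate the correctness of the construction and the indices, not the
magnitude of ecological bias on any real geography.

## Problem sizes and runtime choices

The test suite and the acceptance script run the partition-recovery check
on 20 geographies of 400 cells with a 10% overlap rate, the undercount
calibration on 50 seeded simulations (≈ 3,000 analysis-unit comparisons),
and the fragmentation arithmetic on a constructed 5,632-unit set with 134
planted discontinuous units. These sizes keep every check exact or
well-resolved statistically while running in well under a minute each on a
single core.

## Limitations

* The dissolve's boundary-cancellation contract requires shared borders to
  be collinear between neighbours; noisy digitisations with slivers should
  be snapped upstream.
* A high overlap rate degrades resolution by construction (many merges);
  the decline index makes this visible but the package deliberately offers
  no way to split units again.
* Validation compares aggregates, so compensating errors inside an analysis
  unit are invisible; the common-variable check bounds, but cannot
  localise, linkage error within a unit.
* Only aggregated data are supported. Point or geostatistical data must be
  aggregated to one of the ID systems before entering the pipeline.
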