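---
title: "Phenology-based maize mapping with time-weighted dynamic time warping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology-based maize mapping with time-weighted dynamic time warping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomaize)
```

## The problem

Maize fields trace a characteristic seasonal NDVI trajectory: a low winter
baseline, a rapid green-up after sowing, a high plateau, and senescence
before harvest. Phenology-based classification exploits this: instead of
classifying single images, it compares each pixel's full annual NDVI time
series (46 eight-day composites at 30 m in the intended data) against a
*standard seasonal curve* built from known maize fields, and calls the most
similar pixels maize. `phenomaize` implements that pipeline end to end —
similarity scoring, curve construction, masking, area-constrained labeling —
together with the validation and landscape analyses used to judge the
resulting maps, and a synthetic-landscape generator so every stage can be
exercised and tested without any satellite data.

## Time-weighted dynamic time warping

For a pixel series $X = \{x_1,\dots,x_n\}$ and a standard curve
$Y = \{y_1,\dots,y_m\}$, classical DTW builds the local cost matrix

$$d_{base}(i,j) = |x_i - y_j|$$

and accumulates it over monotone alignments,

$$d_{i,j} = d_{base}(i,j) + \min\{d_{i-1,j},\; d_{i-1,j-1},\; d_{i,j-1}\},$$

with $d_{n,m}$ the distance between the two curves. Plain DTW will happily
stretch a winter-wheat green-up onto a maize green-up months away; the
time-weighted variant adds a logistic penalty on the elapsed time between
aligned observations:

$$d_{base}(i,j) = \omega_{i,j} + |x_i - y_j|, \qquad
  \omega_{i,j} = \frac{1}{1 + e^{-\alpha\,(g(t_i,t_j) - \beta)}}.$$

Defaults are $\alpha = 0.1$ per day and $\beta = 50$ days: alignments less
than ~50 days apart are penalized lightly, alignments much more than 50 days
apart pay a penalty approaching 1 (the scale of the largest possible NDVI
difference), so cross-season warps are effectively forbidden.

Design choices that the recursion above does not pin down:

* **Time function.** $g(t_i, t_j) = |\mathrm{DOY}_i - \mathrm{DOY}_j|$ in
  days, non-circular. With annual stacks and $\beta = 50$ the year-boundary
  wraparound is irrelevant; a circular option
  (`twdtw_params(circular_time = TRUE)`) exists for cross-year uses.
* **Alignment boundaries.** Full-sequence (closed) alignment from $(1,1)$
  to $(n,m)$. Open-ended subsequence variants are out of scope.
* **Tie-breaking.** Backtracking prefers the diagonal predecessor, then up,
  then left — the distance is unaffected, but paths are reproducible.
* **Precision.** Costs accumulate in double precision; at $46 \times 46$
  the result is exact to well below the 1e-9 test tolerance.

The implementation is a small C++ core (a rolling two-row dynamic program
for the per-pixel batch path). Its correctness is pinned by an independent
oracle in the test suite: exhaustive enumeration of all monotone warping
paths for series up to length 6, compared exactly, weighted and unweighted.

## Standard seasonal curves

Per region and season, 50 maize samples are drawn uniformly without
replacement (seeded) and their NDVI series averaged per time step. The
remaining samples — including every non-maize sample — form the validation
set, so accuracy is never assessed on pixels that shaped the curve. Nodata
observations are ignored per step; a step with no valid observation in any
selected sample is linearly interpolated from neighbouring steps (the fused
data this emulates are nominally gap-free, but the synthetic generator can
produce full-column gaps). Reference draws are per run, with the seed
recorded on the curve.

## Classification

1. **Potential-maize mask.** A pixel survives iff its maximum NDVI over the
   growing window is *strictly* greater than 0.3. Default windows: spring
   DOY 60–300, summer DOY 140–300 (the union is used when both seasons are
   present). The mask is a hard pre-filter: masked-out pixels stay
   non-maize no matter the statistics.
2. **Dissimilarity.** Each masked pixel is scored against the spring and/or
   summer standard curve; the smaller distance wins and the winning season
   is recorded (ties break to spring, i.e. list order).
3. **Area-constrained selection.** With a statistical planting area $A$ ha
   and pixel area $a$ m², the $n = \mathrm{round}(A \cdot 10^4 / a)$
   lowest-distance pixels are labeled maize. Rounding minimizes the area
   residual: the identified area matches the statistic to within one pixel
   whenever enough candidates exist; otherwise all candidates are selected
   and the deficit logged. Ties at the cut break by row-major scan order,
   making selections deterministic and nested as the target area grows.

Selection is per region (the provincial analog); the `region_map` argument
carries membership when one stack spans several regions.

## Validation metrics

With confusion counts laid out rows = identified, columns = surveyed, the
package computes

$$\mathrm{PA} = \frac{TP}{TP+FP}\times 100\%,\quad
  \mathrm{UA} = \frac{TP}{TP+FN}\times 100\%,\quad
  \mathrm{OA} = \frac{TP+TN}{TP+TN+FP+FN}\times 100\%.$$

These PA/UA labels are *swapped* relative to the conventional
producer's/user's accuracy definitions. They are implemented verbatim
because they are the definitions under which the bundled provincial
validation tables (`province_confusion()`) reproduce cell-for-cell — the
test suite regresses every UA/PA/OA entry, for both classes, of all 25
bundled confusion matrices. To prevent silent misuse, the conventionally
named `precision` (`TP/(TP+FP)`) and `recall` (`TP/(TP+FN)`) are returned
alongside. Multi-region summaries use the unweighted mean of per-region OA
values; no aggregation is offered for UA/PA because the corresponding
published averages are not the unweighted means of the per-region values
and their aggregation rule is not recoverable.

County-level agreement between statistical areas $SA_i$ and identified
areas $IA_i$ uses the agreement-form coefficient of determination

$$R^2 = 1 - \frac{\sum_i (IA_i - SA_i)^2}{\sum_i (\overline{SA} - SA_i)^2},$$

which can be negative and equals 1 only at exact agreement, the relative
mean absolute error $\mathrm{RMAE} = \sum_i |SA_i - IA_i| / \sum_i SA_i$,
and the OLS slope of $IA$ on $SA$. Zero-variance $SA$ makes $R^2$
undefined; it is reported as `NA` with a warning, never coerced to 0.

## Landscape metrics

Patches are connected components of maize pixels; connectivity defaults to
8-neighbour (the usual remote-sensing choice for field patches) with
4-neighbour available, and the labeling is cross-checked against an
independent image-analysis implementation in the tests. Small patches are
≤ 10 pixels (~0.9 ha at 30 m), large patches > 1000 pixels (~90 ha);
fragmentation class I/II/III corresponds to a small-patch share below 15%,
between 15% and 30% inclusive, and above 30%. Patch sizes always partition
the maize cells — the suite asserts this exactly.

"Continuous planting for over $k$ years" is ambiguous between total maize
years and the longest consecutive run; `planting_frequency()` computes
both and reports category fractions for each. The denominator for those
fractions is the set of cells classified maize in at least one year — a
documented choice, since the alternative (all land cells) dilutes the
fractions by the non-agricultural background.

## The synthetic landscape

`generate_landscape()` produces the full input bundle — NDVI stack, truth
maps, labeled samples, regional statistics — with known ground truth:

* **Mosaic.** Seeded region growing carves the grid into contiguous
  patches with lognormal target sizes (`meanlog 4`, `sdlog 1.5`: median
  ~55 pixels, a realistic mix of smallholder fields and occasional large
  blocks). Patches are assigned to classes by largest remaining deficit,
  so realized class areas match the requested mixture to within one patch.
* **Classes.** Six covers: spring maize (green-up ~DOY 130, senescence
  ~270), summer maize (~170/285) preceded by a winter-wheat bump in
  rotation pixels, rice (deliberately maize-like — flood-depressed early
  NDVI then a steep rise — to exercise the known rice-for-maize confusion
  of NDVI-only phenology), forest (broad plateau), built/bare and water
  (flat). Default mixture: 0.20/0.15/0.15/0.25/0.15/0.10.
* **Observations.** Each pixel samples its class curve at the 46 MODIS-style
  composite days (DOY 1, 9, …, 361) plus i.i.d. Gaussian noise (default sd
  0.02 NDVI). `apply_gaps_and_fill()` optionally deletes observations at a
  given rate and refills them by linear interpolation, mimicking cloud-gap
  filling; the default landscape is gap-free, as the fused product it
  emulates is nominally complete.
* **Statistics.** Regional areas are computed from the truth map, exactly
  conserved by default, optionally perturbed by a stated multiplicative
  log-normal error (`area_error`).
* **Determinism.** All randomness — including inside the C++ region
  grower — flows through R's RNG from a single seed.

What the generator does *not* emulate: spatial autocorrelation of noise,
mixed pixels at field boundaries, spectral distortion from aggressive gap
filling, multi-year crop rotation structure (years are independent draws),
or real phenological variability within a class. Perfect scores on the
synthetic landscape therefore demonstrate the correctness of the machinery
under its own assumptions, not the accuracy attainable on real imagery,
where class overlap and data quality dominate.

## Problem sizes and numerical conventions

The shipped tests run the pipeline at 40–200 pixels on a side with 300–1200
samples per region and reference draws of 25–50, sizes at which every stage
(including the 200 × 200 end-to-end recovery and a 1000-pair brute-force
oracle comparison) completes in seconds while leaving the statistics
well-resolved. The TIFF raster layer stores binary maps as 8-bit (bit-exact
round trip) and NDVI as 32-bit float under an affine \[-1, 1\] → \[0.5, 1\]
value encoding with 0 reserved for nodata, exact to single precision
(~2·10⁻⁷ NDVI); geotransform, timestamps and pixel area ride in a JSON
sidecar, and georeferencing is treated as opaque metadata throughout — the
package never reprojects. Sample coordinates given as lon/lat resolve via
half-open pixel intervals anchored at the upper-left raster corner.

## Known limitations

* NDVI alone cannot fully separate maize from other warm-season crops; the
  rice class in the generator reproduces this failure mode on demand.
* The area constraint transfers any bias in the statistical areas directly
  into the map: with a wrong statistic the best the selector can do is
  rank pixels correctly.
* Alignment is closed (full-sequence); crops whose season straddles the
  calendar-year boundary need the circular time option and a wrapped
  compositing convention not provided here.
* Reference draws are per run; year-to-year curve stability on real data
  is the user's responsibility (the seed is recorded on every curve).
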