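---
title: "Methods: cropland field-boundary mapping at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cropland field-boundary mapping at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures `fieldmapr` implements,
the assumptions behind them, the parameters that matter, and the design
choices made where the method leaves the design open. It states no
empirical numbers beyond those the package's own tests and
`scripts/acceptance.R` compute.

## Grids

All processing happens on three nested geographic grids: 0.05° tiles (the
compositing and segmentation unit), 0.005° primary cells (the labelling and
active-learning unit, 200×200 pixels at native resolution), and 0.000025°
pixels (≈2.8 m at the equator, matching high-resolution CubeSat imagery).
Cell intervals are half-open with the origin at the domain's south-west
corner and row indices increasing northward, so every point belongs to
exactly one cell per level and indices round-trip exactly. We work in plain
geographic coordinates with degree-denominated pixel sizes rather than a
projected metric grid; polygon areas are computed geodesically (WGS84)
rather than by a locally scaled planar approximation, since an exact
geodesic routine was available and removes a latitude-dependent bias.

## Seasonal compositing

A pixel's season of daily observations is reduced to one value per band by
a weighted mean. The haze weight `1/blue²` assumes haze and cloud brighten
the blue band far more than land surfaces do; it is scale-sensitive, so the
package fixes the reflectance domain to [0, 1] (scaled-integer inputs must
be divided by their scale factor at ingest). The shadow weight switches to
`1/NIR⁴` for dates whose NIR falls below the pixel's in-season median
(midpoint convention for even counts, computed over valid dates only).

As written, that switch gives *larger* weight to darker observations, which
conflicts with its narrative purpose of suppressing cloud shadow. We
implement the formula as printed — deliberately, since it is the published
form — and expose `shadow_weight_mode = "dark_downweight"` (`W2 = NIR⁴`) as
a documented alternative. Division by zero is clamped at `ε = 1e-4` in both
weights. Pixels with no valid in-season dates become nodata and propagate
as such. Composites are bounded by the per-band range of their inputs, and
with constant blue and no below-median NIR dates the composite reduces to
the plain mean; both properties are tested.

One consequence of multiplicative inverse weighting worth knowing: the
suppression of a contaminated date depends on the number of clean dates
available. With a full season of clean acquisitions (the generator default
of 8 per season) a single saturated-cloud date moves the composite by well
under 2% relative in every band; with only 2–3 clean dates the shift can be
larger in the blue band, where contaminated and clean values differ by a
factor of five or more.

Composite quality bookkeeping (four 0–3 grades for cloud, shadow, seam
artifacts, and resolution degradation, rescaled by /12) is stored, not
inferred: grading is a human protocol.

## The synthetic landscape generator

The generator exists so that every downstream stage has ground truth. It
emulates, per seed and deterministically:

* a contiguous mosaic of irregular quadrilateral fields (a corner lattice
  with lognormal row/column spacing, interior corners jittered), each
  assigned cropland, herbaceous, or woody cover, with cropland drawn to hit
  a target areal fraction (default 0.3);
* per-date reflectance as the cover's spectrum, interpolated between
  growing- and dry-season endmembers by day of year, scaled by a per-field
  lognormal brightness factor (sd 0.16) plus pixel noise (sd 0.025);
* binary cloud blobs that raise all bands (blue most) and shadow blobs that
  depress NIR — additive masks, not radiative transfer, sufficient to
  exercise the compositing weights;
* labellers of controllable skill: vertex jitter (pixels), field omission,
  and spurious-polygon commission, applied to the true polygons per cell.

The cover spectra are chosen so cropland and herbaceous covers overlap
within each single season but separate in the growing-vs-dry contrast —
the reason the classifier uses two-season features. The overlap, brightness
variability and noise were fixed once, at design time, so that a
starter-sample model at demo scale reaches an F1 around 0.7 with headroom
to improve: a deliberately hard-but-learnable setting that emulates the
ambiguity of real smallholder landscapes. What the generator does *not*
emulate: realistic phenology curves, sensor point-spread/co-registration
effects, topography, and spatially correlated label error. Passing
simulation tests therefore demonstrate internal correctness and qualitative
behavior (orderings, gains), not performance on real imagery.

## Labelling, scoring, and consensus

The assignment quality score is `β0·I + β1·O + β2·F + β3·E + β4·C` with
`β = (0.3, 0.1, 0.2, 0.2, 0.2)` by default (inside-cell agreement
dominates). The five components are defined in this package as follows —
the original component formulas are not public, so these are stated
replacements, each bounded in [0, 1] and equal to 1 for a perfect
assignment:

* `I`: balanced accuracy (mean of sensitivity and specificity) of the
  candidate's rasterized mask against the reference mask; a degenerate
  reference class contributes 1 only if the candidate matches the
  degeneracy;
* `O`: the fraction of candidate area outside the cell that overlaps
  reference-outside area (1 if the candidate stays inside), evaluated on a
  collar half a cell wide;
* `F`: `min(n_cand, n_ref)/max(n_cand, n_ref)` over polygon counts;
* `E`: polygons matched greedily by mask IoU; reference-area-weighted mean
  IoU of their boundaries dilated by 2 pixels;
* `C`: fraction of matched candidate polygons with the correct class.

Rasterization uses the pixel-center rule. Consensus fuses the four
assignment masks as a weight-normalized vote, `p = Σ w_i y_i / Σ w_i`, so
`p` is a probability even though the labeller weights (mean historical QA
scores; prior 0.5 for new labellers) are not a simplex. The classification
threshold is 0.5 with ties resolved to non-field (conservative toward the
majority class). The Bayes risk is fixed as `mean(1 − |2p − 1|)`; it
reproduces the stated endpoints (0 at unanimity, 1 at p = 0.5 everywhere)
and is invariant to relabelling field↔non-field. The scheduler interleaves
one scored QA task after every 5 mapped assignments, never reissues a
training task to the same labeller, and completes a training task at 4
distinct assignments.

## Classification and active learning

Features are the 8 raw two-season bands, their 11×11 moving means, and
their 5×5 moving population standard deviations (24 bands, reflect padding
at edges). The classifier is a random forest with 60 trees and depth 15,
trained on a class-balanced pixel sample (majority class downsampled,
seeded) and predicting soft votes — the fraction of trees voting cropland —
so probabilities are multiples of 1/60. Fits are single-threaded with
derived seeds and reproduce bit-for-bit.

Cell uncertainty is `Q = Σ (p − 0.5)²` over a seeded random subset of
`n_sample = 1000` pixels (the subset size is a package choice; the
criterion only requires "a randomly selected subset"). Low Q = uncertain.
Selection draws `k` cells uniformly from the lowest-Q 30% of the ranking —
the randomization within the top block reduces spatial autocorrelation
among new sites. The loop stops at `max_iterations` (default 3; 2 at demo
scale) or when the validation F1 gain drops below 0.005 — an explicit
stopping rule standing in for the judgment-based stopping the production
workflow used. F1 is the standard harmonic mean of precision and recall
(a parenthetical description of it as a geometric mean elsewhere is treated
as a misstatement); AUC is the Mann–Whitney rank statistic.

## Segmentation

Five steps on the dry-season composite only (labels are drawn against
dry-season imagery, where boundaries are most visible):

1. mean-shift filtering (spatial radius 3 px, range radius 0.1 on
   [0, 1]-scaled bands, ≤10 iterations — parameters fixed here; the method
   specifies none);
2. Sobel gradient magnitudes of the filtered green, red, NIR (each min–max
   scaled per tile so the sum weights sources equally) and of the
   probability map, summed into one edge image;
3. marker-seeded compact watershed (markers on a regular grid, compactness
   0.01) into a fixed number of segments — 6,400 per 2000×2000 tile at
   production scale, 625 per 200×200 tile at demo scale, both keeping mean
   segment size at roughly a third to a half of the expected field size;
4. region-adjacency-graph merging: node means are per-tile min–max
   normalized colors; edges are Euclidean distances between means; the
   globally most-similar adjacent pair merges (pixel-count-weighted means,
   deterministic tie-break on the label pair) while the minimum edge is
   below 0.05 — normalization makes that threshold dimensionless;
5. regions with mean probability strictly > 0.5 are vectorized
   (exact pixel-edge tracing, so areas are conserved), holes removed,
   boundaries simplified by Visvalingam with an effective-area tolerance of
   half a pixel, and polygons merged across tile seams.

Seam merging is performed in raster space: per-tile polygons are
re-rasterized onto the shared grid and connected components spanning more
than one source tile are unioned and re-traced. This is equivalent to a
one-pixel-buffered intersection union on the shared grid, and it is
idempotent; whole-domain versus split-domain segmentations agree in total
field area to well within 2%.

## Assessment

From a stratified reference sample the package forms the area-proportion
error matrix `p_ij = W_i n_ij / n_i` (map strata in rows, reference classes
in columns). Overall accuracy is the diagonal sum; user's accuracy is
row-conditional; producer's accuracy column-conditional. Margins of error
are 1.96 stratified standard errors using the standard good-practice
estimators; the adjusted area of class k is the reference-column sum times
the total mapped area, with
`SE = sqrt(Σ_i W_i² (n_ik/n_i)(1 − n_ik/n_i)/(n_i − 1))`. A matrix can also
be ingested from printed cell percentages plus per-stratum sample sizes
(tallies are reconstructed as `n_i p_ij / W_i`; proportions are
renormalized to absorb print rounding of up to half a percent). Four-level
reference labels ("unsure but likely …") collapse to their binary parents,
with the unsure fraction kept as metadata. Field size/count bias correction
is a ratio estimator: `adjusted = raw × mean(digitized)/mean(segmented)` at
validation cells.

One caveat found while validating against a published assessment table: its
printed producer's-accuracy margins duplicate the user's margins row for
row, so only the overall, user's, and adjusted-area margins can be used to
verify the variance formulas; the producer's variance here follows the
standard stratified estimator.

## Demo scale, runtimes, and problem sizes

The bundled demo grid shrinks only the pixel size (0.00025°), so a tile is
200×200 pixels and a primary cell 20×20; all stage logic is
scale-independent. Simulation studies in the tests and acceptance script
use: 10 seeds for the labelling-quality and active-vs-random comparisons
(20 starter cells, pools of 60, batches of 10, 2 iterations), 5 seeds for
boundary recovery (50 training cells, 625 segments), and 100 replicates for
confidence-interval calibration. These sizes were chosen so the full suite
runs in minutes on one CPU while leaving the compared quantities stable in
sign.

## Known limitations

* The printed shadow-weight form up-weights dark pixels (see above); the
  corrective mode is provided but not default.
* The score components and Bayes-risk formula are stated replacements for
  unpublished definitions; absolute score values are not comparable to the
  production platform's, though orderings behave as expected.
* Greedy global-minimum RAG merging is quadratic in region count in this
  implementation; it is sized for per-tile region counts, not whole-scene
  graphs.
* Field polygons are pixel-edge exact before simplification; very small
  fields (≲3 pixels) can be dropped by simplification, and are logged.
* The reference-sample simulator draws stratified points from the mapped
  classes themselves; it does not model reference-label error, which in
  real assessments is substantial.
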