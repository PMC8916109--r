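# fieldmapr

Desk-scale R implementation of a national cropland field-boundary mapping
workflow for smallholder-dominated landscapes, built around daily 4-band
(blue, green, red, NIR) surface-reflectance imagery. The package is aimed at
agricultural remote-sensing researchers who want to study, test, or adapt
the method's components — compositing, crowdsourced-label quality control,
active learning, and field delineation — without the commercial imagery,
labelling platform, and cluster infrastructure a production run requires.
Every stage runs on a seeded synthetic landscape, so the whole pipeline is
reproducible on a laptop.

## The method

**Weighted seasonal compositing.** Daily scenes within a season are fused
per pixel and band with two multiplicative weights,

    W1_t = 1 / blue_t^2
    W2_t = 1 / NIR_t^4   if NIR_t < median(NIR_1..NIR_i), else 1
    B̄    = Σ_t B_t · W1_t · W2_t / Σ_t W1_t · W2_t

which down-weights hazy/clouded observations (bright blue). The shadow
weight is implemented exactly as printed above; note it *up-weights* dark
pixels, so a `dark_downweight` alternative (`W2 = NIR_t^4`) is provided and
documented, with the printed form as the default.

**Consensus labelling.** Labellers digitize field polygons in 0.005°
primary cells (200×200 pixels at the native 0.000025° resolution). Scored
accuracy-assessment tasks are interleaved 1-per-5 mapped assignments; each
assignment is scored as a weighted sum of five components
(`score = β0·I + β1·O + β2·F + β3·E + β4·C`: inside-cell balanced accuracy,
outside-cell accuracy, fragmentation, boundary/edge agreement, and class
agreement). Four assignments per training cell are fused into a per-pixel
posterior `p(field) = Σ_i w_i y_i / Σ_i w_i`, with `w_i` the labeller's mean
historical score, and cell-level disagreement is summarized by the Bayes
risk `mean(1 − |2p − 1|)` (0 = unanimous, 1 = maximal disagreement).

**Active-learning classification.** A balanced random forest (60 trees,
depth 15) is trained on a 24-feature stack (8 raw two-season bands, their
11×11 means and 5×5 standard deviations) and applied to unlabelled cells.
Cell-level uncertainty `Q = Σ (p − 0.5)^2` over a random pixel subset ranks
cells; new labelling sites are drawn at random from the most-uncertain 30%,
and the loop retrains until the F1 gain stalls or the iteration cap is hit.

**Field delineation.** The dry-season composite is mean-shift filtered;
Sobel edges of its green/red/NIR bands plus the probability map are summed
into one edge image, over-segmented by a marker-seeded compact watershed,
and merged through a region-adjacency graph until no inter-region color
distance is below 0.05. Regions with mean cropland probability > 0.5 become
field polygons, refined by hole removal and Visvalingam simplification, and
merged across tile seams.

**Assessment.** Stratified reference samples yield an area-proportion error
matrix `p_ij = W_i n_ij / n_i`; overall/user's/producer's accuracies and
unbiased class-area estimates come with stratified standard errors
(`z = 1.96` margins). Segmented field size and count statistics are
bias-corrected by the digitized-to-segmented ratio at validation cells.

## Worked example

Recompute the accuracy arithmetic of a published national assessment from
its bundled area-proportion error matrices:

```r
library(fieldmapr)
run_table2_check()[c(5, 10), ]
#>           map  zone overall users_crop producers_crop adjusted_crop_pct
#>     per_pixel Ghana    88.0      67.08          61.71              17.5
#>  segmentation Ghana    86.7      58.19          78.95              17.1
```

Row one: the per-pixel cropland map is 88.0% accurate overall; 67.1% of
mapped cropland is cropland on the ground (user's), and 61.7% of true
cropland was mapped (producer's). Row two: the segmented boundary map
trades commission for omission (58.2% user's vs 78.9% producer's), and the
reference-column sum puts cropland at 17.1% of the mapped area.

Composite a single pixel's two-date series and see the weights act:

```r
sw <- season_window("growing", "2018-05-01", "2018-09-30")
ps <- pixel_series(as.Date(c("2018-06-01", "2018-06-10")),
                   rbind(c(0.10, 0.08, 0.30, 0.40),
                         c(0.20, 0.12, 0.10, 0.50)))
composite_pixel(ps, sw)
#>       blue      green        red        nir
#> 0.10063593 0.08025437 0.29872814 0.40063593
```

The first date (clear: blue 0.10, weight 100×39.06) dominates the second
(hazier: blue 0.20, weight 25×1), so the red composite lands at 0.2987,
near the clear observation's 0.30.

Run the full demo pipeline (synthetic landscape → composites → consensus
labels → active learning → field polygons → accuracy report):

```r
cfg <- load_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "fieldmapr"))
cfg$out_dir <- tempfile()
manifest <- run_pipeline(cfg)   # ~15 s; 15 hashed artifacts
```

A thin CLI wraps the same functions
(`inst/scripts/fieldmapr run|compose|label|train|segment|assess|experiment|table2-check`).

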