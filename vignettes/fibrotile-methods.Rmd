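---
title: "Automated tile-based Ashcroft grading: models, parameters and design choices"
author: "fibrotile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tile-based Ashcroft grading: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrotile)
```

## The problem and the pipeline

Histopathological severity of pulmonary fibrosis in the bleomycin mouse
model is conventionally graded on the Ashcroft scale: an ordinal score
from 0 (normal alveolar architecture) to 8 (total fibrous obliteration of
the field), assigned by an expert reading trichrome-stained lung
sections. Manual grading is slow and rater-dependent, which motivates an
automated, tile-based version of the same protocol:

1. the scanned whole section is **downscaled by 50%**,
2. split into **512 × 512 pixel tiles** on a row-major grid,
3. each tile is assigned a class — a grade 0–8 or a **non-alveolar**
   class for tiles dominated by large bronchi or vessels,
4. non-alveolar tiles (and, in this implementation, tiles containing
   almost no tissue) are excluded, and
5. the whole-section **composite score** is the tile-count-weighted mean

   $$S \;=\; \frac{\sum_{g=0}^{8} g\,n_g}{\sum_{g=0}^{8} n_g},$$

   where $n_g$ is the number of included tiles of grade $g$.

Agreement between automated and manual grading is quantified with
confusion matrices and Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$. The package additionally implements
positive-pixel %-area morphometry for collagen stains and whole-lobule
stereology (Archimedes lobule volume from displaced-fluid mass, and
marker volume = mean serial-section %-area × lobule volume).

## The tile classifier

The classification unit is a tile raster; the classifier contract is a
probability vector over the 10 classes (`gradeLevels()`), normalised to
1. Two implementations satisfy it:

* **`reference_small_cnn`** (default): three conv(3×3)/ReLU/max-pool
  blocks with 8, 16 and 32 filters on tiles resized (area-average) to
  32 × 32, a 64-unit dense ReLU layer, and a 10-way softmax, trained
  with Adam (step size $10^{-3}$, batch 32) on softmax cross-entropy for
  **25 epochs**, with rotation (multiples of 90°), horizontal/vertical
  flip and multiplicative brightness augmentation. Validation accuracy
  is recorded after every epoch and the best-validation epoch's weights
  are returned. The network is implemented directly in R (im2col
  convolutions); no deep-learning framework is available in the
  supported environment, and at the package's desk scale this trains in
  well under a minute per corpus on one CPU. An `inception_v3`
  architecture option exists in the configuration for fidelity to the
  original tool but requires a framework backend and is rejected with an
  informative error here.

* **`baselineTextureClassifier`**: a deterministic, training-free
  nearest-centroid classifier in a fixed 5-feature texture space
  (collagen-palette fraction, tissue fraction, mean luminance, edge
  density, ring score). Features are scaled by their pooled
  *within-class* standard deviation (diagonal-LDA style), so features
  that are tight within a class and move across classes dominate the
  metric. It serves as a fast, exactly reproducible oracle in pipeline
  tests, not as the production classifier.

### Data assembly

The annotated tile corpus is **split 75% / 20% / 5%** into training,
validation and test partitions, stratified per class with
largest-remainder apportionment (each class's split sizes are within one
tile of exact proportionality; remainders go to the larger fraction).
Classes are then **balanced by resampling**: minority classes are
oversampled with replacement up to the majority count.

One deliberate deviation from the source protocol's sentence order: the
original description balances classes *before* splitting. Oversampling
first would let bit-identical duplicates of one tile land in both the
training and the test partition, leaking labels and inflating kappa, so
this package splits first and balances the training partition only. An
optional `groupIds` argument additionally confines whole sections to a
single partition, preventing intra-section texture correlation from
leaking across splits.

Augmentation magnitudes are not stated in the source protocol beyond the
transform names; brightness is drawn from ±20% here, and both choices
are exposed in `trainingConfig()`.

### Tie-breaking and exclusions

At prediction, each tile receives the argmax class; ties resolve to the
*lower* grade (non-alveolar last), which deterministically under-calls
rather than over-calls fibrosis. Two exclusion rules apply identically
in the composite score: non-alveolar predictions, and tiles whose tissue
fraction is below 5% (blank glass would otherwise dilute the score
toward 0, since empty tiles would be classified as *something*). Both
exclusion counts are reported separately. A section whose tiles are all
excluded raises an error rather than returning 0 — a silent 0 would
masquerade as "no fibrosis".

## Geometry conventions

Coordinates are 0-based, half-open, (row, col) = (y, x) everywhere.
Tiling covers the downscaled raster with
$\lceil h/512 \rceil \times \lceil w/512 \rceil$ tiles; edge tiles are
padded with background white and record their in-bounds
`valid_fraction`, so the tile grid remains congruent with the section
for heatmap rendering, and reassembling the unpadded tile footprints
reproduces the raster bit-exactly. Downscaling uses area averaging (box
filter) — deterministic, alias-free, and exact on constant rasters —
with round-half-away-from-zero dimension rounding and a floor of 1
pixel; microns-per-pixel metadata is divided by the factor. Whether
tissue detection preceded downscaling in the original tool is unstated;
this package downscales first.

The tissue mask calls a pixel tissue when its BT.601 luminance is below
0.92 of full scale **or** its HSV saturation exceeds 0.08. Both
thresholds are package inventions (background handling is not described
in the source protocol) and are exposed as arguments.

## The synthetic histology generator

No imaging data accompanies the original study, so the package carries a
procedural generator that makes the full pipeline testable end to end.
A tile is rendered from three palette colours (near-white airspace, pink
tissue, blue collagen) as:

* a **Voronoi-ridge alveolar lattice** — walls appear where the two
  nearest alveolar centres are nearly equidistant — whose wall thickness
  increases strictly with grade (default 1.2 → 4.4 px across grades
  0–8);
* **fibrotic masses** — random disks coloured collagen — covering a
  strictly increasing target area fraction per grade (default 0, 0.06,
  0.14, 0.24, 0.36, 0.50, 0.64, 0.80, 1.00 for grades 0–8), so grade 0
  has no collagen and grade 8 is fully obliterated;
* i.i.d. Gaussian channel noise (sd 8 of 255), clipped to [0, 255] —
  chosen so nearest-palette pixel classification, and hence the
  generator's oracles, stay computable with tolerance;
* the **non-alveolar class** renders a large ring (a bronchus/vessel
  surrogate) rather than a texture, guaranteeing geometric separability
  from the grade continuum.

Default tiles are 64 px — the desk scale at which the whole train/score/
validate cycle runs in seconds — while the scoring geometry for real
sections remains 512 px; the classifier resizes any square tile to its
input size, so the two coexist. Per-grade class proportions of the
original annotation corpus are unpublished; synthetic corpora default to
uniform counts per class.

What the generator does **not** emulate: real stain physics, scanner
artifacts, the histological semantics of the Hübner grade criteria
(honeycombing, fibrous bands), or inter-section staining variability.
A green end-to-end test therefore establishes that the pipeline's
mechanics — assembly, training, prediction, exclusion, aggregation —
recover a known ordinal ground truth; it does not certify accuracy on
real slides, whose validation numbers (kappa 0.78–0.83 in the source
study) depend on an unreleased slide corpus.

All generators are pure functions of (inputs, seed): child seeds are
drawn from a parent seed's stream, and the global RNG state is saved and
restored around every seeded operation.

## Agreement statistics

`cohenKappa()` defaults to the **unweighted** statistic (the source
protocol says "Cohen's kappa" without qualification); linear and
quadratic ordinal weightings are computed alongside in reports, since
either is defensible for an ordinal scale and the original choice is
unstated. Whether the published section-level concordance was computed
on rounded section scores or pooled tile labels is also unstated, so
`agreementReport()` provides both levels: tile-level labels directly,
and section-level scores rounded half-up to integer grades for kappa
with Lin's concordance coefficient reported unrounded alongside.
Non-alveolar tiles are excluded from agreement by default (they are
excluded from scoring), with a flag to include them as an 11th class.

## Morphometry and stereology

Positive-pixel rules per stain are explicit hue/saturation/luminance
windows; the thresholds used by the original commercial software are
unpublished, so the real-stain presets ship clearly labelled
*uncalibrated*, while the `synthetic` profile uses the exact
nearest-palette rule so that area-fraction oracles are computable. The
"total sectional area" denominator is interpreted as the *tissue* area
(background glass excluded via the tissue mask), with a flag for the
full raster.

Lobule volume follows the Archimedes displaced-fluid protocol,
volume = mass / density, with density defaulting to 1.0 g/mL (the
displacement fluid is unnamed in the protocol). Whole-lobule marker
volume multiplies the mean serial-section %-area (sections every
300 µm) by the lobule volume; the 300 µm spacing is carried as metadata
only — no Cavalieri estimator is fitted, because volume comes from
displacement, not from section areas.

## Numerical choices and degenerate inputs

* Composite score of an all-excluded map: error, never 0.
* Kappa with chance agreement $p_e = 1$: defined as 1 if $p_o = 1$,
  else 0, and flagged degenerate.
* Argmax ties: lowest grade, non-alveolar last.
* Half-up rounding (`floor(x + 0.5)`) wherever a rounding rule matters
  (section-score discretisation, downscale dimensions), avoiding R's
  banker's rounding.
* Probability vectors normalise to 1 within 1e-6 by contract; the
  centroid classifier's softmax over negative squared distances and the
  CNN's softmax both guarantee this analytically.
* TIFF support is a minimal baseline codec (uncompressed 8-bit
  gray/RGB), validated against an independent reference implementation;
  pyramidal WSI formats are out of scope.

## Known limitations

* The real-stain positive-pixel presets cannot claim numerical
  equivalence with the original study's commercial-software settings.
* The reference network is a small CNN, not Inception-v3; at desk scale
  and on synthetic fixtures this is the right fidelity/runtime
  trade-off, but the configuration surface keeps the architecture
  pluggable.
* Biological results of the source study (group mean scores, %-area
  time courses) require the original slides and are not reproduction
  targets of this package.
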