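---
title: "Quantifying the tumor immune microenvironment from RCM videos"
author: "rcmtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the tumor immune microenvironment from RCM videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcmtime)
```

## The problem

Reflectance confocal microscopy (RCM) images skin at cellular resolution,
label-free and in vivo, to a depth of roughly 0.25 mm. In skin tumors the
same videos that clinicians use diagnostically also contain the dynamic
ingredients of the tumor immune microenvironment (TiME): blood vessels
(visible as regions whose backscatter fluctuates as blood flows),
leukocytes trafficking along vessel walls (bright spots rolling, crawling
or adhering), and infiltrating immune cells (bright dendritic or
round-ellipsoid shapes against the tissue texture). `rcmtime` turns those
videos and frames into numbers — vessel count, area and diameter,
trafficking counts per temporal window, immune-cell area densities — and
turns manually graded feature tables into TiME *phenotypes* (combinations
of HIGH/LOW inflammation and vasculature) and treatment-response
predictions.

Because the package's correctness cannot be established on clinical data
alone, every stage has a synthetic twin: seeded generators plant vessels,
moving cells, immune-cell shapes and phenotype clusters with known ground
truth, and the test suite measures recovery of that truth.

## Video stabilization

Hand-held in vivo imaging moves. Stabilization is two-step:

1. **Linear pre-alignment.** Every frame is registered to the first frame
   with a rigid transform (affine available) estimated from matched
   difference-of-Gaussians blob keypoints at two scales, described by
   normalized image patches, matched by normalized cross-correlation with
   a mutual-best and ratio test, and fit by least squares with iterative
   outlier trimming. A frame with fewer than 4 consistent matches keeps
   the identity transform and a warning — deliberately conservative, since
   a wrong linear fit is worse than none. Resampling pads out-of-view
   pixels with 0, which downstream stages treat as the *blank* value.
2. **Automatic cropping.** On the temporal-minimum image, the boundary
   line (top/bottom row, left/right column) with the most blank pixels is
   removed iteratively until every boundary line is at most
   three-quarters blank. Ties are broken top, bottom, left, right — the
   rule needs a deterministic order and nothing in the procedure favors
   one side. Cropping below 16 px (the floor is exposed as `min_size`)
   errors rather than silently producing unusable frames.
3. **Chained nonlinear registration.** Frame t+1 is histogram-matched to
   the stabilized frame t (256 quantile bins) and registered to it by
   multi-resolution demons registration: 4 pyramid levels, iterations
   100/50/10/1 from coarsest to finest, Gaussian smoothing of the
   displacement field (sigma 1 px) after every update. Chaining (each
   frame registers to the previously *transformed* frame) keeps the whole
   sequence in one geometry; a second cropping pass then removes
   everything not in view throughout the movie. The demons variant is the
   standard (non-diffeomorphic) intensity-driven update
   `u = diff * grad / (|grad|^2 + diff^2)`; with the small smooth
   deformations seen in these videos the extra machinery of a
   diffeomorphic variant buys nothing. The pyramid is capped so the
   coarsest level stays at 16 px or more.

The `residual_motion_score` (mean per-pixel temporal variance after
stabilization) is reported rather than thresholded: rejecting unrecoverable
videos (e.g. strong axial motion) is an operator decision.

On synthetic videos carrying a 4 px smooth deformation the procedure
removes over half of the temporal variance; the floor is set by speckle,
which no registration should remove.

## Blood-vessel segmentation

The segmentation assumption is that, once frames are registered, *areas of
high variation between consecutive frames are vessels*. The variation map
is built as: per-frame Gaussian smoothing (sigma 1 px, suppressing
speckle), a temporal finite-impulse-response high-pass `(0.5, -1, 0.5)`
across consecutive frames, the absolute response median-filtered with a
7 x 7 window, per-frame mean subtraction with negatives clipped at 0 (this
removes slowly varying areas), and accumulation over the video. Two
conventions are fixed here: the *absolute* FIR response is used because the
kernel is sign-indefinite and variation is a magnitude; and accumulation is
the *mean* over frames rather than the sum, so maps from videos of
different lengths live on one scale. The kernel is a second difference: it
annihilates constant and linearly drifting intensities exactly, which the
tests assert to machine precision.

Vessels are then Otsu-thresholded on the map, closed with a disk of radius
3 px (the closing element is a configuration knob; the procedure only says
"morphological closing"), and filtered by component size: only components
between 0.1% and 10% of the frame area survive, implemented as
`ceiling(0.001 * N) <= size <= floor(0.10 * N)` pixels. Metrics use
8-connectivity; per-component diameters are twice the Euclidean distance
transform sampled along the component's skeleton (Zhang-Suen thinning),
converted to microns at 1.33 px/um. A 10 px thick bar therefore reports a
10 px mean diameter, which is the oracle the tests use.

A stride option evaluates every k-th frame only; it exists because manual
ground-truth segmentation was practical only on temporally thinned videos,
and whether the automated path should consume every frame or every 10th is
ambiguous — both are supported, the default is every frame.

## Leukocyte trafficking

Trafficking quantification chains four stages:

- **Background subtraction**: per pixel, the median over a 6 s window
  centered on the current frame (truncated at the ends; the window is
  converted to frames from the video's frame interval and must be at least
  3 frames). Static texture cancels; cells moving fast enough to occupy a
  pixel for about a frame survive at essentially full amplitude.
- **Spot detection**: difference-of-Gaussians tuned to a 7.5 px radius
  (sigma = radius/sqrt(2), ratio 1.6), positive local maxima refined to
  subpixel positions by a 2-D quadratic fit. Each detection's *quality* is
  the implied blob amplitude — the closed-form center response of a matched
  Gaussian blob makes the DoG response invertible to an amplitude — times
  an arbitrary-unit scale (default 4). The 1.6 detection threshold is
  meaningful only relative to this calibration: it sits between the
  speckle noise floor (about 0.2–0.5 on synthetic videos) and the response
  of a planted trafficking cell (about 2.4).
- **Linking**: frame-to-frame linear assignment with squared-distance
  costs, a 20 px maximum match distance, and no splitting, merging or gap
  closing. Each frame pair is one square assignment problem with
  birth/death slots at cost `(1.05 * 20)^2` — the standard LAP-tracker
  construction — solved by a Jonker–Volgenant shortest-augmenting-path
  solver written for this package and tested against brute-force
  enumeration on every instance small enough to enumerate.
- **Filtering**: three temporal windows of 3/4/5 frames (0.6/0.8/1.0 s at
  5 frames per second) with per-window minima on displacement
  ([20.5, 22.5, 22.5] px), maxima on motion consistency (mean turning
  angle, [58, 58, 58] degrees), and minima on mean quality
  ([1.6, 1.65, 1.75]). A tracklet's duration is counted as
  `n_detections * frame_interval` so that a 3-frame tracklet at 5 fps
  spans 0.6 s, matching the identification of "3–5 frames" with
  "0.6/0.8/1.0 s"; the alternative `(n-1)` convention would demand one
  extra detection per window. Zero-length steps are skipped in the turning
  average, and an immobile tracklet has consistency 0 (it is removed by
  the displacement gate, not the angle gate).

Filters for longer windows are uniformly at least as strict, so counts are
monotone non-increasing from the 0.6 s to the 1.0 s window — asserted as an
invariant. On synthetic videos with 6 planted cells moving 6 px/frame the
pipeline recovers the count exactly at low speckle.

## Immune-cell segmentation

Single RCM frames are segmented pixelwise into three classes: dendritic
cells and macrophages (class 1, elongated/branched), round-ellipsoid
leukocyte-like cells (class 2), background (class 3, including everything
unlabeled — partial labeling is folded into background rather than masked
out of the loss). The segmenter is a trainable multiscale pixel
classifier: each pixel carries Gaussian smoothings at sigmas 1/2/4/8 px,
difference-of-Gaussians between adjacent scales, gradient magnitude and a
local standard deviation, and a random forest (`ranger`, 200 trees by
default, seeded) classifies pixels; training samples a class-stratified
subset of pixels per image. This is the classical trainable-segmentation
design for cellular imagery; the two planted morphologies differ exactly
in the local scale and anisotropy the feature bank measures. Images are
resampled to a configurable working size (256 px default; bilinear for
images, nearest-neighbor for labels).

Evaluation is one-vs-rest Dice per class with a macro average (a class
absent from both maps scores 1), and the derived density features are the
class-1, class-2 and combined percentages of all pixels — which sum with
the background percentage to exactly 100, a tested identity. At desk
scale (25 synthetic 96 px images, 20/5 train/validation) the held-out
macro Dice exceeds 0.95; the acceptance bar is 0.7.

## Phenotyping

Manually graded TiME features (six canonical features — number of vessels,
dilated vessels, trafficking, intratumor/peritumor/perivascular
inflammation — on an ordinal 0–3 scale) are standardized per feature
(z-score; the shared bounded scale makes correlation-matrix PCA the
appropriate choice), decomposed by PCA, and the fewest leading components
explaining at least 95% of variance are retained (at least two, so both
phenotype axes exist). Ward-linkage hierarchical clustering runs on the
retained scores; the k-means consolidation step some HCPC implementations
offer is off by default for reproducibility.

**Choosing the cluster count.** With `n_clusters = "auto"` the cut over
k = 2..6 maximizes the relative loss of within-cluster inertia between
successive partitions, with inertia read off the Ward dendrogram heights.
Two guards matter on ordinal data: integer grades produce many duplicate
rows, so cuts beyond the true structure reach *exactly zero* inertia and
would win a naive argmax. Partitions whose parent holds less than 5% of
total inertia are therefore not split further, and the first local maximum
of the relative-loss profile is taken — the first elbow, not the deepest
degenerate one. On planted 3- and 4-cluster tables at 6+ noise-SD
separation this recovers the true k and an adjusted Rand index of 1 across
seeds and noise levels.

**Axis naming.** The vascular axis is the retained component on which the
summed squared-loading contribution of the vascular features is largest;
the inflammation axis likewise, and the two must differ — if both blocks
dominate the same component the function refuses and asks for manual axis
assignment rather than guessing. Each axis is sign-oriented so its
defining features load positively, and a cluster is HIGH on an axis if its
centroid is above 0 (the grand mean in standardized space) — the published
analysis assigned names by inspecting the PCA scatter, and the centroid
rule is the reproducible version of that judgement. One geometric caveat
is worth knowing: with exactly three phenotype corners (vascular-high,
inflammation-high, both-high) the two feature blocks are intrinsically
anti-correlated across clusters, so correlation-PCA components can rotate
toward sum/difference directions and the block-to-axis attribution
becomes unstable. Axis naming is exercised on tables containing all four
corners (with the vascular separation larger than the inflammatory one,
which is also the structure the published PC1/PC2 shows); on pure
three-corner tables the cluster *recovery* is still exact, but axis names
should be reviewed against the contribution plot.

Projection of new lesions standardizes with the *training* means and SDs,
multiplies by the loadings, and assigns the nearest centroid in retained-PC
space (ties to the lowest cluster index), inheriting its label — this is
how treated patients are phenotyped on a previously fitted model.

## Agreement statistics

Two chance-corrected coefficients validate the features: Cohen's kappa for
reader-vs-reader agreement on the ordinal grades, and a linearly weighted
Gwet coefficient for RCM-vs-histology presence. "Linearly weighted AC1" is
read as Gwet's weighted generalization (sometimes labelled AC2) with
weights `1 - |i-j|/(K-1)`: the unweighted AC1 has no weight matrix, and
with identity weights the implementation reduces to it exactly (a tested
identity). Gwet's chance term uses category propensities
`pi_k = (p_k. + p_.k)/2` and `p_e = T_w / (K(K-1)) * sum pi_k (1 - pi_k)`,
which stays calibrated under the extreme prevalence this data shows (some
features present in every lesion, where kappa is undefined). Binary
presence collapses grade 0 to absent and 1–3 to present; the two-reader
average is the rounded mean (round-half-up), a convention the source
procedure leaves open. Spearman correlation (average ranks, two-tailed
t-approximation) serves the feature-vs-expression analyses.

## Response modeling

Treatment response (binary: complete vs incomplete regression under
topical TLRA imiquimod) is modeled with a linear probability model — OLS
of the 0/1 response on the graded features, classified at 0.5 — rather
than logistic regression: the source analysis fits linear regressions and
reports Gaussian-looking AIC values, and at n = 13 the linear model's
out-of-bag behavior is also far better conditioned. Performance is
estimated by leave-one-out cross-validation; a fold whose training half
loses one class entirely is skipped with a warning rather than failing,
which is reachable at this sample size. The AIC convention is fixed as
`n * ln(RSS/n) + 2(p + 2)` (intercept and variance parameter counted);
appending a predictor orthogonal to the response and the other predictors
raises it by exactly 2, a closed-form property the tests assert.

Greedy forward selection adds, per iteration, the candidate with the best
out-of-bag score under either criterion: `specificity_first` (maximize
specificity, ties by accuracy then lower AIC — the clinically motivated
mode: a false "will respond" costs a patient months of ineffective
treatment) or `aic_first` (minimize AIC, ties by accuracy). Alphabetical
order is the final tie-break so selection is fully deterministic. Exact
linear-separability checks (interval disjointness in 1-D, convex-hull
disjointness in 2-D, margin = half the hull distance) support the
feature-pair analyses.

## The synthetic-data generators

`generate_rcm_video` emulates exactly the properties the pipeline keys on:
a static smoothed-noise tissue texture; sinuous tubular vessels (radius
6 px) in separate horizontal bands whose interior intensity jitters
frame-to-frame (SD 0.12 — the temporal-variation signal); bright Gaussian
particles (amplitude 0.6, size matched to the 7.5 px detection radius)
moving along vessel centerlines at a configurable speed, staggered so they
avoid the vessel ends when the itinerary fits (reflection there is the
fallback); multiplicative gamma speckle with shape `1/contrast^2`
(contrast 0.15 by default — coherent-imaging speckle without modeling the
optics); a bounded Gaussian random-walk global drift; and a smooth random
deformation field (coarse-grid noise, sinusoidal in time), applied after
the drift with zero padding. The default 0.2 s frame interval makes the
3/4/5-frame windows span 0.6/0.8/1.0 s; the clinical frame rate is not
fixed by the published description, so it stays a parameter.

What the generators do *not* emulate: optical sectioning and depth,
melanin/collagen contrast, vessel pulsatility, cell-shape deformation
during rolling, z-motion, or spatially correlated speckle. Passing the
planted-truth tests therefore demonstrates that the algorithms implement
their specifications and recover structure under the stated noise model —
not that clinical accuracy matches the published validation figures, which
were measured against manual annotation of patient videos.

`generate_immune_labelmap` plants separated round/ellipsoid cells
(class 2) and branched polyline cells (class 1) brighter than the textured
background, with exact label maps. `generate_feature_table` draws lesions
as cluster means plus Gaussian noise, rounded and clipped to 0–3, with
per-cluster Bernoulli response labels — the planted clusters, means and
response probabilities are returned as truth.

## Numerical conventions and edge cases

- "Blank" is exactly 0 — alignment padding introduces the only zeros in
  float input.
- Median filters truncate their window at borders (2-D spatial and 1-D
  temporal alike).
- Otsu runs on the min-max-normalized map with 256 levels; an all-equal
  map yields an empty mask with a warning, since no threshold exists.
- The variation map is invariant to adding a constant and scales linearly
  with intensity scaling — both exact, both tested.
- Empty masks give zero metrics; both-empty masks have Dice 1.
- Detection local maxima use a strict 3x3 comparison with an epsilon so
  plateaus do not double-fire; subpixel offsets are clamped to half a
  pixel.
- LAP costs are kept finite: infeasible links get a penalty larger than
  any feasible assignment can accumulate.
- Grades outside 0–3, non-binary responses, duplicate feature names,
  zero-variance features (named in the error), singular designs (collinear
  features named) and degenerate perfect fits all error early with
  specific messages.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to exercise every code path with comfortable margins:
256 x 256 videos with 50 frames for vessel recovery, 12 frames with 6
planted cells for trafficking, 128 px videos for registration, 25 images
of 96 px for segmenter training, and 27–32-lesion tables for phenotyping —
the same order of magnitude as the clinical cohorts the method targets
(27 BCC, 13 melanoma, 13 treated lesions).

## Known limitations

- Published patient-level validation figures (reader-agreement
  coefficients, cohort variance percentages, clinical model accuracies)
  derive from patient data that is not redistributable here and are not
  recomputed; the package reproduces the *procedures* and verifies them on
  planted truth.
- Detection quality is calibrated in arbitrary units; the printed
  thresholds transfer to real videos only up to that calibration.
- The demons implementation targets smooth in-plane deformation; severe
  axial (z) motion is out of scope and only surfaces via
  `residual_motion_score`.
- Axis naming on three-corner phenotype geometries is intrinsically
  ambiguous (see above); the implementation refuses rather than guesses
  when the blocks collide on one component.
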