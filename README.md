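# rcmtime

Quantification and phenotyping of the tumor immune microenvironment (TiME)
from in vivo reflectance confocal microscopy (RCM) of skin tumors.

RCM records label-free, cellular-resolution videos of skin in patients. In
and around tumors these videos capture the dynamic side of anti-tumor
immunity that static biopsies miss: blood vessels (regions whose
backscatter fluctuates as blood flows), leukocytes trafficking along
vessel walls (bright moving spots), and infiltrating immune cells.
`rcmtime` implements a complete analysis chain for this data:

- **Video stabilization** — rigid/affine keypoint pre-alignment, automatic
  cropping of blank borders on the temporal-minimum image, then chained
  multi-resolution demons nonlinear registration (4 pyramid levels,
  iterations 100/50/10/1) with histogram matching.
- **Blood-vessel segmentation** — temporal-variation mapping (Gaussian
  smoothing sigma 1 px; temporal high-pass FIR `(0.5, -1, 0.5)`; 7x7
  median; per-frame mean subtraction), Otsu thresholding, morphological
  closing and 0.1%/10% component-size gates; vessel count, area fraction
  and skeleton-based diameters in microns (1.33 px/um).
- **Leukocyte trafficking** — rolling 6 s median background subtraction,
  subpixel difference-of-Gaussians spot detection (radius 7.5 px), LAP
  linking (max 20 px, no gap closing/splitting/merging) via a
  Jonker-Volgenant solver, and tracklet filtering in three temporal
  windows (0.6/0.8/1.0 s) with displacement >= [20.5, 22.5, 22.5] px,
  motion consistency <= 58 deg and mean quality >= [1.6, 1.65, 1.75].
- **Immune-cell segmentation** — a trainable multiscale-feature pixel
  classifier (random forest) for three morphology classes
  (dendritic/macrophage, round leukocyte-like, background), with
  per-class/macro Dice and area-density features.
- **TiME phenotyping** — z-score standardization, PCA retaining >= 95%
  variance, Ward clustering on principal components with an automatic
  elbow cut (k = 2..6) or a forced k, variable contributions, Inflam/Vasc
  axis naming (`Inflam^HIGH Vasc^LOW`, ...) and projection of new lesions
  onto a fitted model.
- **Agreement statistics** — Cohen's kappa, linearly weighted Gwet
  agreement coefficient, binary grade collapse, Spearman correlation.
- **Treatment-response models** — leave-one-out cross-validated linear
  probability models with greedy forward selection under
  specificity-first or AIC-first criteria (`AIC = n ln(RSS/n) + 2(p+2)`),
  plus exact 1-D/2-D linear-separability checks.
- **Synthetic data** — seeded generators for RCM-like videos (flickering
  tubular vessels, moving particles, speckle, drift, smooth deformation),
  immune-cell label maps and graded 0-3 feature tables with planted
  cluster structure, so the whole chain is testable against known truth.

## Worked example

```r
library(rcmtime)

## 1. simulate an RCM video with known ground truth
sim <- generate_rcm_video(256, 256, n_frames = 12, n_vessels = 2,
                          n_trafficking_cells = 6,
                          particle_speed_px_per_frame = 6,
                          speckle_contrast = 0.05, seed = 11)
video <- sim$video
#> video_stack: 12 frames of 256 x 256 px, 0.2 s/frame, 1.33 px/um

## 2. vessels from temporal variation
mask <- segment_vessels(variation_map(video))
vessel_metrics(mask)
#> vessel_metrics: 2 vessels, area fraction 0.0686
#>  component area_px mean_diameter_um max_diameter_um
#>          1    2272         8.621739        10.63318
#>          2    2221         8.543025        10.52632
dice_coefficient(mask, sim$truth$vessel_mask)
#> [1] 0.821

## 3. leukocyte trafficking per temporal window
count_trafficking(video)[1:3]
#> window_0.6s window_0.8s window_1.0s
#>           6           6           6

## 4. phenotyping a graded feature table (27 lesions, 3 planted clusters)
tab <- generate_feature_table(27, list(
  list(mean = c(3, 3, 3, 0, 0, 0), n = 11, response_prob = 0),
  list(mean = c(0, 0, 0, 3, 3, 3), n = 7,  response_prob = 1),
  list(mean = c(3, 3, 3, 3, 3, 3), n = 9,  response_prob = 0.5)),
  noise_sd = 0.3, seed = 2)
fit_phenotype_model(tab$table)
#> phenotype_model: 27 samples, 2/6 PCs retained (97.6% variance), 3 clusters

## 5. response modeling with forward selection
forward_select(tab$table, tab$table$feature_names,
               mode = "specificity_first", max_features = 2)[[2]]
#> response model [number_of_vessels + perivascular_inflammation]:
#>   sens 0.80, spec 1.00, acc 0.93, AIC -65.32
```

Reading the numbers: both planted vessels are found (Dice 0.82 against
the planted mask; the mean diameter of ~8.6 um reflects the planted 6 px
half-thickness at 1.33 px/um after median-filter erosion), all six planted
trafficking cells are counted in every window, the three planted
phenotype clusters are recovered from two principal components, and the
forward-selected two-feature response model separates the planted
responder cluster with perfect specificity.

A thin command-line wrapper over the same functions ships in
`inst/cli/time-scope.R` (subcommands `simulate`, `stabilize`, `vessels`,
`trafficking`, `phenotype`, `agreement`, `respond`, `run`).

The methods vignette (`vignettes/time-quantification.Rmd`) documents the
models, parameter conventions, numerical choices and the limits of what
the synthetic tests demonstrate.

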