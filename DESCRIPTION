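Package: rcmtime
Title: Tumor Immune Microenvironment Quantification and Phenotyping from
    Reflectance Confocal Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dynamic tumor immune microenvironment (TiME) features
    from in vivo reflectance confocal microscopy (RCM) of skin tumors and
    derives inflammation/vasculature phenotypes. Provides two-step video
    stabilization (keypoint pre-alignment, automatic border cropping, chained
    demons nonlinear registration), temporal-variation blood-vessel
    segmentation with count/area/diameter metrics, leukocyte-trafficking
    quantification (rolling-median background subtraction, subpixel
    difference-of-Gaussians spot detection, linear-assignment linking,
    tracklet filtering), trainable pixelwise immune-cell segmentation,
    PCA plus hierarchical clustering phenotyping with Inflam/Vasc axis
    naming, chance-corrected agreement statistics (Cohen's kappa, linearly
    weighted Gwet coefficient), and leave-one-out cross-validated
    treatment-response models with forward feature selection. Includes
    seeded synthetic-data generators (RCM-like videos, immune label maps,
    graded feature tables) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
SystemRequirements: C++11
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
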