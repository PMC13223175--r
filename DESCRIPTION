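Package: voxmanova
Title: Voxelwise Multivariate GLM Analysis of Multimodal Quantitative MRI Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-multivariate analysis of co-registered quantitative MRI
    parameter maps (MTsat, PD, R1, R2*). Fits per-voxel univariate and
    multivariate general linear models with age, gender, total intracranial
    volume and scanner as regressors, tests age effects through Wilks' lambda
    with exact or Rao-approximate F inference, decomposes multivariate effects
    into canonical vectors, controls the family-wise error rate by voxel-level
    Bonferroni or permutation of the maximum statistic (Freedman-Lane scheme),
    compares thresholded maps via their union, overlap partition and Cohen's
    kappa, performs split-half cross-validation, and summarises regions of
    interest through nuisance-adjusted partial correlations with age and
    peak-voxel canonical weights. Includes a synthetic multimodal phantom
    generator so the entire pipeline runs and is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
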