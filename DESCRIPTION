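Package: polcropsar
Title: Integrated PolSAR and Optical Crop Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Crop classification from co-registered quad-polarimetric SAR
    covariance data and multispectral optical reflectance. Implements the
    Hoekman polarization-basis intensity transform of the 3x3 lexicographic
    covariance matrix, the Yamaguchi four-component power decomposition,
    the radar vegetation index, NDVI, sliding-window entropy texture,
    PCA-based feature reduction, min-max feature integration in several
    stacking modes, supervised classification by RBF-kernel support vector
    machines and by the complex-Wishart maximum-likelihood rule, and full
    confusion-matrix accuracy assessment (overall accuracy, kappa, user's
    and producer's accuracies, one-vs-rest TP/FN/TN/FP rates). A seeded
    synthetic-scene simulator (multi-look complex-Wishart speckle over a
    labeled field mosaic with class-specific optical reflectances) makes
    every stage testable without satellite data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, e1071, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
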