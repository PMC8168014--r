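Package: lhatrace
Title: Brain-Wide Quantification of Neurons Projecting to the Lateral Hypothalamus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for quantifying retrogradely
    labeled neurons projecting to the lateral hypothalamic area (LHA) in serial
    coronal sections. Provides a self-contained toy atlas with landmark-based
    plate assignment and affine/thin-plate-spline section registration, polygon
    parcellation into per-region crops, a Gaussian-derivative feature bank with
    random-forest pixel classification and regression-forest density counting
    ("learning to count"), injection-site volumetry and cohort quality control,
    50k count normalization and LHA-atrophy compensation, the associated
    statistical battery (two-way ANOVA with Sidak post-hoc comparisons,
    one-way ANOVA with Tukey HSD, pooled-variance t-tests from raw data or
    summary statistics), and misfolded-protein burden scoring by rolling-ball
    background subtraction and Renyi-entropy auto-thresholding. A synthetic
    cohort generator with exact ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    car,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
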