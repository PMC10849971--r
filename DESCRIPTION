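Package: embryoquant
Title: Quantification of Compartment Geometry, Perimeter Polarity and
    Haematopoietic Foci in Stem-Cell Embryo Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying fluorescence
    images of stem-cell-derived embryo models: detection and size
    filtering of wild-type (epiblast-like) compartments, radial
    intensity profiling from the compartment perimeter, circular
    rolling-average polarity calling for anterior (CER1) and posterior
    (TBXT) markers with anterior-posterior axis classification,
    quantification of haematopoietic foci (per-cell marker objects,
    haemoglobin ratios, CD34 area fraction, z-stack marker
    distributions, uni-/multilineage focus rules), relative qPCR
    expression (2^-ddCt), and marker-gene-list similarity statistics
    (hypergeometric overrepresentation with Benjamini-Hochberg
    correction, and a Jaccard-difference statistic with an empirical
    sampling null). Ships a synthetic-scene generator with ground-truth
    manifests so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    generics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
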