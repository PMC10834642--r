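Package: saikoqams
Title: Single-Marker Quantification and Fingerprint Similarity for
    Saikosaponin Quality Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality-evaluation toolchain for multi-component herbal
    chromatography built around quantitative analysis of multiple
    components by a single marker (QAMS). Implements relative calibration
    factors and their stability across instrument-condition grids,
    internal-reference selection, single-marker and external-standard
    quantification with content calculation, analytical validation
    statistics (linearity, LOD/LOQ from signal-to-noise, precision RSD,
    spike recovery), chromatographic fingerprinting (peak detection,
    common-peak matching, congruence similarity against a median
    reference), and content-matrix chemometrics (PCA and Ward
    hierarchical clustering). A synthetic peak-table and chromatogram
    generator with linear detector responses, multiplicative area noise,
    condition-driven drift and latitude-linked batch structure provides
    the study conditions end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
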