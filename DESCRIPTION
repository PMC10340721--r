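Package: mitoquant
Title: Quantitative 3D Microscopy of Mitochondrial Dynamics, Autophagy and
    Mitophagy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of multi-channel 3D fluorescence
    z-stacks of mitochondria and autophagy-related vesicles. Provides a
    synthetic-data generator with scripted ground truth that emulates
    confocal acquisition geometry, intensity binarization with size
    filtering, detection and localisation of mitochondrial fission and
    fusion events between consecutive time-lapse frames, colocalisation
    classification of vesicular puncta into autophagosome, lysosome,
    autolysosome and mitophagy (automitosome, mitolysosome,
    automitolysosome) classes, regression-adjusted colocalisation colour
    mapping, and hierarchical per-cell statistics with one- and two-way
    ANOVA followed by Fisher's LSD post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
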