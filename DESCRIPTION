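Package: vleaf
Title: Volumetric Leaf Area Measurement and Validation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating leaf area of whole leaf piles from
    hydrostatic volumetry. Leaf volume is obtained by Archimedes suspension
    weighing or on a Specific Gravity Bench (SGB), and volumetric leaf area
    (VLA) is the volume divided by the sampled mean lamina thickness. The
    package implements the volumetric calculations (with optional midrib
    exclusion), pixel-count optical leaf area (OLA) from scan rasters as the
    reference method, method-agreement statistics (range-normalised RMSE,
    ordinary least squares, Pearson correlation, Bland-Altman limits of
    agreement), and the virtual resampling experiments (pile analysis and
    thickness-sampling error). A seeded synthetic wheat-leaf generator with
    known ground truth (parametric silhouettes, rendered scans, simulated
    weighing records) supports validation of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    png,
    tiff,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
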