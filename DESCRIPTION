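Package: spectromicrobe
Title: Linking Canopy Reflectance Spectra to Soil Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for relating airborne imaging spectroscopy of
    vegetation canopies to the composition and diversity of the underlying soil
    microbiome. Provides hyperspectral preprocessing (buffer averaging,
    wavelength resampling, vegetation-index masking, bad-band removal, vector
    normalisation), derivation of microbial response variables from PLFA
    biomarker tables and 16S ASV count matrices (group sums and ratios,
    rarefaction, dominant-phylum relative abundances, richness, Bray-Curtis
    NMDS axes, Hellinger and centred log-ratio transforms), core-to-plot
    aggregation with empirical-Bayes shrinkage, temporal alignment of
    multi-source observations, association statistics (variation partitioning
    with permuted partial redundancy analysis, Spearman and partial Spearman
    correlation with Bonferroni correction, collinearity screening), and an
    ensemble partial least squares regression workflow with PRESS-based
    component selection, outlier screening, predictive uncertainty, and
    variable-importance-in-projection interpretation. A seeded synthetic-data
    module generates NEON-like multi-plot datasets with known ground truth so
    every stage can be tested by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    withr
Suggests:
    caret,
    jsonlite,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
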