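Package: rifasel
Title: Feature Extraction and Dual-Pathway Feature Selection for UAV
    Multispectral Detection of Fire-Ant Mounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discriminating red imported fire-ant (Solenopsis
    invicta) mounds from surrounding land-cover classes in five-band UAV
    multispectral imagery. Builds a 38-feature stack per analysis unit
    (five reflectance bands, NDVI/SAVI/PPR vegetation indices, and six
    gray-level co-occurrence matrix texture measures per band), extracts
    pixel-level and object-level labeled tables from regions of interest,
    and ranks and prunes features along two complementary routes: a
    linear route (one-way ANOVA F-scores with greedy Pearson |r| > 0.7
    redundancy removal) and a nonlinear route (random-forest recursive
    feature elimination with maximal information coefficient > 0.7
    redundancy removal). The four method-by-scale configurations are
    integrated into a normalized importance heatmap, retention
    frequencies, and averaged rankings. Includes a seeded synthetic-scene
    and synthetic-table generator for validating the selection framework
    against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    pracma,
    ranger,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
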