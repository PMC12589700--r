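Package: conduitscaling
Title: Allometric Scaling and Climate Response of Xylem and Phloem Conduits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how xylem vessel and phloem sieve-element
    anatomy scale with distance to the stem tip and respond to climate across
    woody angiosperm species. Computes conduit traits (equivalent and hydraulic
    diameters, density, lumen fraction) from raw lumen-area measurements, fits
    generalized least squares and phylogenetic GLS allometries with Pagel's
    lambda and variance structures selected by BIC, detrends traits, computes
    phylogeny-corrected Pearson correlations with a jointly maximized lambda,
    reduces bioclimatic variables by principal component analysis, and compares
    four causal path models (null, indirect, direct, full) by d-separation
    tests, Fisher's C and the C-statistic information criterion, with
    replication over multiple candidate phylogenies. Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    nlme,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
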