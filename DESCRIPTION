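Package: isophene
Title: Stable Isotope Phenotyping of Single Cells from Multi-Isotope NanoSIMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for taxonomy-independent phenotyping of single microbial
    cells measured by nanoscale secondary ion mass spectrometry (NanoSIMS)
    after stable isotope probing. Reads per-mass ion-image stacks and
    region-of-interest (ROI) tables, applies dead-time correction, plane
    alignment and accumulation, computes isotope (13C/12C, 15N/14N, 33S/32S,
    34S/32S) and elemental (C/CN, S/CN) ratios with instrumental
    fractionation correction, partitions cells into isotope phenotypes with
    from-scratch implementations of ten clustering algorithms validated by
    the Calinski-Harabasz index and silhouette widths, and cross-tabulates
    phenotypes against independent FISH taxon labels. Includes a synthetic
    data generator (Gaussian mixtures in ratio space, Poisson ion counting,
    full ion-image scenes) so the entire pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
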