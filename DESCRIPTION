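Package: spatiomic
Title: Spatiotemporal Analysis of Root and Soil Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of spatiotemporal structure in plant-associated
    microbial communities sampled under nested split-plot field designs. Provides
    OTU-table input/output, rarefaction and alpha diversity; Bray-Curtis,
    geographic and temporal distances with lagged root-soil similarity; nested
    PERMANOVA with type III sums of squares, omega-squared effect sizes,
    restricted permutations and beta dispersion; NMDS ordination with
    Procrustes/PROTEST concordance; generalized dissimilarity models with
    monotone I-splines, permutation importance, backward selection, deviance
    partitioning and bootstrap spline uncertainty; occupancy-abundance core
    microbiome selection with Sloan neutral-model fitting; and a synthetic
    community generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vegan,
    permute,
    biomformat,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
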