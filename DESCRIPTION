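Package: seacomm
Title: Biogeography and Assembly Processes of Marine Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of microbial OTU count data across oceanographic
    surveys: rarefaction and alpha diversity (richness, Shannon, Faith's
    phylogenetic diversity, nearest taxon index), Bray-Curtis beta
    diversity with ordination and permutation tests (ANOSIM, Mantel,
    Procrustes/PROTEST), distance-decay regression with slope-difference
    permutation tests, and quantification of community assembly processes
    (heterogeneous and homogeneous selection, dispersal limitation,
    homogenizing dispersal, ecological drift) from beta nearest taxon
    index and Bray-Curtis Raup-Crick null models.  Includes a synthetic
    community generator that produces phylogenies, two-region seascapes
    and OTU tables under known assembly regimes, so that every stage of
    the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    grDevices,
    picante,
    vegan,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
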