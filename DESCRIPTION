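Package: lakeco
Title: Community Ecology Inference for Lake Microeukaryote Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing taxa-by-sample amplicon count tables from
    lake surveys along salinity gradients: rarefaction and alpha diversity,
    Bray-Curtis beta diversity with distance-decay regressions, PERMANOVA
    and (partial) Mantel permutation tests, null-model community assembly
    partitioning (beta-nearest-taxon index and Bray-Curtis-based
    Raup-Crick), Levins niche breadth, signed co-occurrence networks with
    random-matrix-theory thresholding, topology, stability and
    keystone-node analysis, trophic-group differential abundance, and
    cross-validated random-forest biomarker models.  A synthetic community
    generator with phylogenetically conserved salinity niches makes the
    whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils,
    vegan,
    withr
Suggests:
    picante,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
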