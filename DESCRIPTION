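Package: strawdecomp
Title: Distance-Decay, RMT Co-Occurrence Networks and CAZyme Attribution
    for Straw-Decomposition Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for plant-residue (straw) decomposition
    microbiome studies. Builds Bray-Curtis community dissimilarities and
    standardized straw-chemistry Euclidean distances, fits distance-decay
    regressions of community similarity on chemistry distance with
    permutation tests for slope sign and for slope differences between a
    focal taxonomic group (e.g. Actinobacteria) and other groups,
    constructs random-matrix-theory (RMT) thresholded signed co-occurrence
    networks with topology indices and focal-group link accounting, and
    computes CAZyme taxonomic-attribution metrics (RPKM normalization,
    per-phylum class profiles, average-CAZyme ratios, Z-score variation
    across decomposition stages, substrate-group roll-ups and
    soil-fertility contrasts). A synthetic-data generator with known
    ground truth emulates the field design (3 sites x 5 stages x 12
    replicates) so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
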