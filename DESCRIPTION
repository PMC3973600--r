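Package: rhizonet
Title: Interolog Networks and Dual-Platform Differential Expression for
    Rhizobial Bacteroid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs protein-protein interaction networks for a target
    bacterial genome by transferring reference-organism interactions across
    bidirectional-best-hit ortholog maps (interologs), calls differentially
    expressed genes from RNA-Seq counts (RPKM with an exact binomial count
    test and Benjamini-Hochberg correction) and from microarray intensities
    (SAM-style permutation test), overlays expression on the network to
    extract fold-change-thresholded and seed-centred subnetworks, scores
    active modules by aggregated z-transformed p-values, and summarises
    results with hypergeometric set enrichment, COG tallies, per-replicon
    proportion tables and sliding-window genome profiles. Includes a
    synthetic-data generator with planted orthologs, a planted network
    module and planted differential expression so that every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
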