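Package: ssnfam
Title: Protein Subfamily Delineation from Sequence Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scalable delineation of large protein families into subfamilies
    using all-versus-all local-alignment sequence similarity networks (SSNs)
    indexed over a grid of E-value thresholds, rule-based subfamily calling
    (minimum size and taxonomic diversity), and validation of candidate
    partitions with a per-subfamily profile hidden Markov model library
    scored by precision and recall. Includes a synthetic protein-family
    generator with known subfamily structure for end-to-end benchmarking,
    BLAST tabular import/export, GraphML/edge-list network export, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
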