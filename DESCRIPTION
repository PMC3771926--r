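Package: conregid
Title: Unsupervised Discovery of Conserved Regions in Protein Sequence
    Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers highly conserved sequence regions shared among
    protein sequences, including remote homologs and multi-domain
    proteins, without supervision. Sequences are grouped by all-against-all
    local alignment into a connectivity graph, split into maximal cliques
    to avoid domain chaining, aligned per clique, and scanned for
    conserved regions by substitution-matrix conservation scoring with
    median-filter smoothing. Region profiles are searched back against all
    sequences as position-specific scoring matrices, redundant regions are
    merged, and the result is a binary sequence-by-region association
    table together with clustering and domain-recovery evaluation metrics
    and a planted-domain synthetic data generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
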