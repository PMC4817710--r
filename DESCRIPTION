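Package: medecomp
Title: Minimum Entropy Decomposition of Marker-Gene Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised partitioning of quality-filtered marker-gene
    amplicon datasets (for example 16S rRNA reads) into fine-scale,
    homogeneous sequence units. Per-column Shannon entropy identifies
    information-rich alignment positions, a dynamically normalized entropy
    threshold decides convergence, and a minimum substantive abundance
    filter removes noise-driven lineages -- with no pairwise alignment or
    fixed similarity threshold. Produces sample-by-unit observation
    matrices, representative sequences, and the full decomposition
    topology. Includes a template-based amplicon read simulator with a
    substitution error model for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
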