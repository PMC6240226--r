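Package: orthodiverge
Title: Ortholog Resolution and Divergence Analysis for Transcriptome-Based
    Species Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A species-comparison pipeline for assembled transcriptomes of
    microbial eukaryotes. Contigs from multiple samples are clustered into
    homologous groups by single-linkage over an all-vs-all similarity
    search, within-sample paralogs are resolved at a 2% uncorrected
    p-distance cutoff with neighbor-joining gene trees, and the resulting
    orthologous subgroups are summarized by minimum, maximum and average
    intra- and inter-species p-distances. Groups are partitioned by copy
    status and by matches to single-copy reference-genome clusters built
    with reciprocal best hits, and single-copy DNA barcode candidates are
    mined against the 2% barcode-gap threshold. A sequence simulator with
    known ortholog/paralog truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
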