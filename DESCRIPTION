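Package: ribopool
Title: Ribotype Pool Analysis and Statistical-Parsimony Networks for
    Hybrid Detection from rDNA Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting hybridization and introgression in plants
    from intragenomic ribosomal DNA (ITS) variation sequenced as paired
    amplicon pools. Implements sliding-window quality trimming, overlap
    merging of read pairs, exact dereplication into ribotypes, read-count
    thresholds separating major from minor ribotypes with integer-percentage
    summaries, statistical-parsimony (TCS-style) ribotype networks with a
    probability-of-parsimony connection limit, and shared-ribotype parentage
    reports for putative hybrids. A seeded paired-FASTQ simulator with known
    ribotype composition (including hybrid pools mixing two parents) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
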