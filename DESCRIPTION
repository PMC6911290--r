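Package: ltrnest
Title: Simulation and Analysis of Nested LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying nesting of long terminal repeat (LTR)
    retrotransposons: a synthetic-genome simulator that plants Ty3/gypsy and
    Ty1/copia elements with target site duplications, age-dependent LTR
    divergence and configurable insertion-site biases; a structural detector
    that recovers full-length elements by direct-repeat search and recursive
    excision of nested copies; curation filters (reverse-transcriptase domain
    presence, exact target site duplications) and reference-panel family
    classification; region-preference statistics with chi-squared
    goodness-of-fit tests and false discovery rate correction; molecular
    dating from LTR divergence; target-site-duplication motif profiling;
    approximate-palindrome enrichment testing against base-shuffled controls;
    and nucleosome occupancy prediction from periodic dinucleotide content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
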