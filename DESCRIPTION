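Package: crisprsieve
Title: CRISPR Array Detection, Cas Locus Typing and False-CRISPR Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects CRISPR repeat-spacer arrays in prokaryotic genomes with a
    CRT-style seed-and-extend scanner (including extension of partial terminal
    repeats), groups cas gene annotations into typed loci, quantifies
    CRISPR/cas co-location, and separates real CRISPR arrays from
    CRISPR-mimicking repeat elements: tandem repeats, Staphylococcus aureus
    repeat (STAR)-like elements carrying the T[G/A/T]TGTTG[G/T]GGCCC[C/A]
    signature, and simple low-complexity repeats. Ships a synthetic-genome
    simulator that plants arrays, false elements and cas loci with full ground
    truth, so every stage of the pipeline can be benchmarked without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
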