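Package: AnchorCorrect
Title: Reference-Free Error Correction of Clustered Long cDNA Reads
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Error correction for Oxford Nanopore cDNA reads that have been
    pre-clustered into gene families. Each read is partitioned into
    anchor-bounded intervals by solving a weighted interval scheduling
    problem over paired positional minimizers, and each interval is
    corrected against a partial-order-alignment consensus using frequency-
    and context-aware trusted variants, so that reads from different
    isoforms of a gene jointly correct their shared exons while
    low-frequency true variants (for example allele-specific SNPs) are
    retained. Includes a read simulator with controlled per-transcript
    depth and error profile, and an evaluator measuring error rate,
    miscorrection, and overcorrection against known transcripts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, ErrorCorrection, Transcriptomics, LongRead
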