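Package: circpipe
Title: De Novo Identification and Quantification of Circular and Fusion
    Circular RNAs from RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for de novo identification and abundance
    quantification of circular RNAs (circRNAs), including fusion
    circRNAs arising from chromosomal translocations, from single-end
    and paired-end RNA-Seq reads. Candidate back-splice junctions are
    detected from chimeric (split-read) alignments and arbitrated by a
    trainable maximum-entropy splice-site model; abundance is estimated
    by realigning reads to a doubled pseudo-circular reference and
    counting junction-spanning alignments. A seeded benchmark simulator
    generates synthetic genomes with planted splice sites, circRNA and
    linear reads, and fusion circRNA events with truth tables, so the
    whole pipeline can be exercised offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
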