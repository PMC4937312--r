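Package: sirnascope
Title: Region-Partitioned Quantification of Transgene-Induced Small RNA Silencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analysis toolkit for transgene-induced trans-silencing in
    Paramecium-like systems. Represents gene models, truncated transgene
    constructs and the primary/secondary siRNA region partition they induce;
    simulates seeded synthetic cohorts (references, small-RNA and long-RNA
    reads, qPCR Ct tables) with per-read truth labels; maps small RNAs by
    exact matching in two rounds and classifies them by region, strand,
    length and exon-exon junction overlap; normalizes read counts with a
    knockdown-aware total-count-scaling factor; estimates per-intron splice
    rates of long reads with an isoform-guided aligner and a 4-bp
    intron-overlap rule; detects spliced antisense introns; and computes
    ChIP-qPCR enrichment relative to input with reference-locus and histone
    H3 normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
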