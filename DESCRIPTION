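Package: discChIP
Title: Tissue-Context Analysis of ChIP Binding Events in Imaginal Discs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies per-tissue transcription-factor binding events as
    tissue-shared or tissue-specific with a dual false-discovery-rate
    threshold rule, and characterizes each class by interval co-occurrence
    statistics (binned hypergeometric tests), genomic-region breakdown,
    degenerate-consensus and spaced-dimer motif content, central motif
    enrichment, evolutionary conservation profiles, ultraconserved-element
    overlap, enhancer-catalog overlap, and five-state chromatin enrichment.
    Includes a seeded synthetic-data generator that emits every input the
    pipeline consumes together with a ground-truth manifest, and an
    orchestrator that runs the full analysis deterministically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
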