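Package: entforge
Title: Building and Benchmarking Enhancer-to-Target-Gene Definitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs genome-wide enhancer-to-target-gene definitions
    (EnTDefs) by combining enhancer-region sources with enhancer-gene link
    evidence (pair tables, paired-anchor interactions, chromatin loops),
    enumerates the full combinatorial space of definition configurations,
    assigns genomic regions (peaks) to genes under any definition, performs
    negative-binomial gene-set enrichment testing with an approximate score
    test or an exact likelihood-ratio test, and evaluates and ranks
    definitions by F1-score concordance with transcription-factor Gene
    Ontology annotations, by labeled enhancer-gene pair benchmarks, and by
    an interceding-gene analysis.  A deterministic synthetic-regulome
    generator provides toy genomes, ontologies and peak sets with planted
    signal so that every pipeline stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    splines,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
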