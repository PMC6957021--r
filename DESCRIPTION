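Package: mnvrescue
Title: Rescue Multi-Nucleotide Variants Miscalled as Independent SNVs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for variant call sets in which
    multi-nucleotide variants (MNVs) have been miscalled as independent
    single-nucleotide variants. Clusters nearby SNV calls, establishes
    cis/trans phase from spanning sequencing reads, merges cis clusters
    into single delins records with HGVS-style nomenclature, recomputes
    codon-aware protein consequences, and reports where naive per-SNV
    annotation and merged annotation disagree (potential false-positive or
    false-negative diagnostic results). A bundled deterministic simulator
    generates synthetic references, transcript models, planted-MNV reads
    and truth sets so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    SummarizedExperiment,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
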