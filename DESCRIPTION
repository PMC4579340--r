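Package: promoterTurnover
Title: Evolutionary Birth and Death of Promoters Between Two Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the evolutionary fate of transcription start site
    (promoter) intervals between two focal species using dual-source alignment
    projections resolved against outgroup species, quantifies expression
    turnover across matched tissue panels, computes gene-level compensatory
    turnover statistics, and measures selective constraint (derived allele
    frequency tests) and genomic enrichments (repeat coverage, per-base
    conservation-score profiles) against mappability-aware permutation nulls.
    Includes a synthetic two-lineage evolution simulator that emits every
    input format together with ground-truth event labels, and an end-to-end
    pipeline driver with a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
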