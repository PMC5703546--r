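Package: dhsdyn
Title: DNase Hypersensitivity Dynamics Across Differentiation Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of DNase-seq open-chromatin dynamics across staged cell
    differentiation. Derives replicate-consensus hypersensitive sites from
    per-replicate peak calls, computes merged-union Venn membership and
    gained/lost site calls between stages, classifies sites into
    promoter/exon/intron/intergenic genomic partitions, quantifies
    co-occupancy with transcription-factor ChIP peak sets, builds strand-aware
    TES-flank and quantile-scaled metagene signal profiles with summit-based
    gene grouping, and cross-tabulates those groups against fold-change
    expression classes. Includes a seeded synthetic-data generator with
    planted ground truth for end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
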