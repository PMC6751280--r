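Package: splicedyn
Title: Isoform-Level Transcriptome Dynamics Across Developmental Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for isoform-level analysis of a staged developmental
    transcriptome built from full-length transcript models: classification
    of alternative splicing events (intron retention, exon skipping,
    alternative 5'/3' splice sites, mutually exclusive exons), retained
    intron characterization and premature termination codon calling under
    the 50-nt rule, per-gene intron-retention transcript (IRT) value
    dynamics, poly(A) site clustering and signal-motif enrichment, fusion
    candidate filtering, and stage-level expression dynamics with k-means
    temporal clustering. Includes a fully seeded synthetic data generator
    that plants known splicing events, poly(A) sites and expression
    archetypes so every stage of the pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
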