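Package: txforge
Title: Reference-Guided Transcriptome Annotation Improvement and
    Stage-Comparison Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to update a reference gene annotation from assembled
    transcript fragments (transfrags) and to compare transcriptomes of two
    developmental stages. Implements intron-chain class coding of transfrags
    against a reference ("=", "j", "u"), acceptance of novel isoforms and
    novel intergenic genes under support, isoform-fraction and CPM filters,
    strand-aware measurement of 5'/3' gene extensions, ORF discovery with
    completeness typing (complete, 5'/3'-partial, internal), rescue of
    unmapped reads with poly-A/T trimming and length/GC filters, greedy
    contig deduplication at a nucleotide identity threshold, repeat-class
    expression quantification with fractional multi-mapper assignment and
    pair-level ambiguity exclusion, TMM normalization, a negative-binomial
    Wald test for differential expression, and hypergeometric gene-set
    enrichment. A synthetic-data generator plants novel genes, UTR
    truncations and differential-expression effects with a machine-readable
    truth ledger so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    MASS,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
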