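Package: v2gtier
Title: Post-GWAS Variant-to-Gene Prioritization with Colocalization,
    Regulatory Confluence and Evidence Tiering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A post-GWAS framework for linking non-coding risk variants to
    their effector genes. Starting from GWAS summary statistics and a phased
    haplotype reference panel, the package prunes genome-wide significant
    variants to pairwise-independent tags, expands each tag into an
    LD-defined analysis region, classifies candidate variants against a
    hierarchical disjoint genome partition, performs Bayesian
    GWAS-eQTL colocalization with approximate Bayes factors (H0-H4
    posteriors and per-SNP posteriors), scores transcription-factor
    binding-site disruption from position weight matrices, requires
    confluent enhancer and tissue-context support, validates candidate
    pairs in silico (effect-allele harmonized directionality, McNemar
    comparison, enhancer-promoter interaction and TAD dual-anchor overlap,
    independent eQTL replication), and ranks variant-gene pairs on an
    additive evidence tier. A synthetic-data module generates LD-structured
    haplotypes, summary statistics with planted causal configurations, and
    truth-consistent annotation bundles so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, GenomeWideAssociationStudy, FunctionalGenomics,
    GeneRegulation, SNP, Bayesian
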