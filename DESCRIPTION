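Package: methylpanel
Title: Targeted Bisulfite Sequencing Analysis of AML Methylation Subgroups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for targeted bisulfite sequencing of leukemia
    cohorts: per-CpG methylation matrices with coverage and completeness
    filters, correlation-distance Ward clustering with bootstrap cluster
    support, extraction of regions uniquely differentially methylated in a
    designated subgroup, strand-aware TSS-window assignment of regions to
    genes with a Spearman anti-correlation methylation-expression filter,
    and downstream cohort statistics (expression categorization against
    healthy donors, Fisher's exact and Mann-Whitney tests, Kaplan-Meier and
    log-rank survival analysis, cumulative incidence of relapse with death
    as a competing risk). Includes a synthetic cohort generator that plants
    subgroup-specific differentially methylated regions and
    methylation-coupled gene expression for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cmprsk,
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
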