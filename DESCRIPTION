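Package: gwasqtl
Title: Integrating Genome-Wide Association Scans with QTL Linkage Intervals
    in Structured Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining genome-wide association study (GWAS) evidence
    with quantitative trait locus (QTL) likelihood intervals from linkage
    mapping, developed around seed-size genetics in sorghum diversity panels.
    Provides a structured-population genotype and phenotype simulator with
    haplotype-block linkage disequilibrium and planted QTL effects; a
    mixed-linear-model association scan with marker-based kinship random
    effects and principal-component covariates (with optional kinship
    compression); linkage-disequilibrium r-squared matrices, genome-wide decay
    estimation, and Bonferroni and LD-bin multiple-testing thresholds;
    association-hotspot calling from LD-linked significant markers; anchoring
    of QTL likelihood intervals to physical coordinates via flanking aligned
    markers and interval algebra (overlap, merge, refinement ratio); and exact
    Fisher tests of QTL-GWAS overlap within a genome and of cross-taxa
    trait-locus correspondence over collinear ortholog pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    vcfR,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
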