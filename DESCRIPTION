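Package: meqtlmap
Title: Methylation QTL Mapping with Permutation FDR and Annotation Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for mapping methylation quantitative trait
    loci (meQTLs) from array beta values and SNP dosages: probe quality
    filtering, quantile normalization across technical replicates, rank-based
    inverse-normal transformation, principal-component correction for hidden
    confounders, additive single-locus cis and trans association scans,
    permutation-based false discovery rate estimation using the best signal
    per probe, a Bayesian hierarchical model for annotation and distance
    enrichment of meQTLs, and methylation-expression integration (promoter
    methylation correlation, matched-control eQTL overlap, and
    methylation-residual eQTL re-analysis). Includes a synthetic-data
    generator that emulates the statistical structure of population
    methylation array studies so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
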