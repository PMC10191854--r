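Package: l1mosaic
Title: Somatic LINE-1 Retrotransposition Analysis in Clonal Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying somatic LINE-1 (L1) retrotransposition in
    phylogenies of single-cell-derived clones. Implements validation and
    classification of mobile-element insertion calls (solo-L1, partnered and
    orphan 3' transductions, twin-priming and foldback breakpoint anatomy),
    reconstruction of early developmental phylogenies from binary genotype
    matrices of postzygotic mutations, developmental staging of branches,
    retrotransposition-rate estimation normalized by endogenous point
    mutations with exact Poisson inference, source-element fingerprinting
    and per-allele activity metrics, population allele frequency of source
    elements, L1 promoter CpG methylation scoring and epigenotype calling,
    genomic-feature bin enrichment of insertion sites, and a synthetic-data
    generator that emulates the statistical structure of clonal whole-genome
    data so that every stage of the pipeline can be exercised and calibrated
    without access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
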