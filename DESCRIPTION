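Package: multiprs
Title: Multi-Ancestry Polygenic Risk Score Construction, Combination and
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating multi-ancestry polygenic
    risk scores (PRS) for case/control outcomes such as Alzheimer disease.
    Implements native LD clumping plus p-value thresholding over a
    parameter grid with coefficient-of-variation model selection,
    inverse-variance fixed-effects meta-analysis of GWAS summary
    statistics, per-study PRS scoring with allele harmonization and
    genomic-region masking (e.g. the APOE locus), three multi-study
    combination strategies (meta-analysis first, unweighted summation,
    and weighted summation with weights trained in an independent
    cohort), train-referenced standardization for transfer to external
    cohorts, and association/AUC evaluation restricted to unrelated
    individuals.  A synthetic-cohort generator (Balding-Nichols allele
    frequency drift, block LD, liability-threshold phenotypes, family
    structure) makes the full pipeline testable without access-restricted
    genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    pROC,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
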