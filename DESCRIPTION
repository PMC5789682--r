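Package: crossprio
Title: Cross-Species Prioritization of Candidate Genes in Rare-Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates rare-variant evidence from a human exome cohort with
    differential gonadal gene expression from a model organism to nominate
    candidate disease genes. Implements minor-allele-frequency filtering of
    variants of unknown significance, fold-change classification of FPKM
    expression matrices, trimmed-mean-of-M-values (TMM) normalization and
    replicate-based differential testing of count matrices, ortholog-mediated
    cross-referencing with a configurable multi-criteria priority score,
    knockout-dependence annotation, hypergeometric gene-set over-representation,
    qPCR standard-curve quantification, and a synthetic-data generator that
    emulates the full study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    limma,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'crossprio-package.R'
    'crossref.R'
    'enrichment.R'
    'expression-analysis.R'
    'pipeline.R'
    'qpcr.R'
    'simulate.R'
    'tables-io.R'
    'utils.R'
    'variant-filtering.R'
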