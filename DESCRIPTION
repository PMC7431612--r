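Package: gutTrait
Title: Two-Part Microbiome-Phenotype Association, Microbiability and
    Co-Abundance Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Association analysis between gut microbial taxa and a
    quantitative host phenotype such as finishing weight. Implements a
    two-part (presence/absence plus abundance-when-present) association
    model with Stouffer meta-analysis, min-p selection, permutation
    skewness correction and FDR control; a cross-validated additive
    predictor estimating the fraction of phenotypic variance explained by
    the microbiome; SparCC compositional correlation estimation with
    permutation significance, co-abundance group (CAG) definition by Ward
    clustering and PERMANOVA, and CAG-phenotype correlation; high/low
    extreme-group contrasts (Wilcoxon rank-sum, Student's t, Spearman)
    with FDR correction; and a synthetic zero-inflated compositional data
    generator that emulates the study design end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
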