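Package: poolcross
Title: Heterotic Pool Definition and Genomic Prediction of Single Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A marker-platform-agnostic pipeline for hybrid breeding
    analysis in crops without an established heterotic-pool history.
    Starting from parental SNP dosage matrices (delimited tables, VCF or
    HapMap), the package applies a two-branch quality-control cascade,
    characterises population structure (Rogers genetic distance, principal
    coordinate analysis, k-means clustering, Mantel and Kendall concordance
    statistics), fits a GCA/SCA genomic diallel mixed model with
    marker-derived kernels, derives heterotic groups and testers from
    specific combining ability, and predicts untested single crosses with
    an additive-dominance GBLUP model validated by replicated k-fold
    cross-validation. A synthetic-data generator emulates a structured
    inbred panel genotyped on several marker platforms and evaluated in
    multi-environment augmented-block trials, so the whole chain can be
    exercised and tested without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    vegan,
    withr
Config/testthat/edition: 3
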