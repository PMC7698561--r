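Package: metaboselect
Title: Variable Selection, Pathway Annotation and Validation for Untargeted
    LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative variable-selection pipeline for untargeted LC-MS
    metabolomics feature tables. Implements QC-based preprocessing (feature
    filters, QC support-vector-regression drift correction, probabilistic
    quotient normalization, KNN imputation, QC-optimized generalized-log
    transform, mean centering), five selection routes (paired Wilcoxon with
    Benjamini-Hochberg correction, OPLS-DA with VIP, WRT-PLS with significance
    multivariate correlation, CARS-PLS-DA, sparse PLS-DA) inside a patient-
    stratified double cross-validation with consensus feature sets,
    Mummichog-style m/z adduct annotation with primary-ion enforcement,
    pathway enrichment with Fisher/EASE tests and permutation validation, and
    correlation-network analysis. Ships a synthetic paired-cohort generator
    with known ground truth so the behaviour of sparse versus all-relevant
    selectors can be demonstrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    MASS,
    ggplot2
Config/testthat/edition: 3
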