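Package: bccstrat
Title: Sex-Stratified Analysis of Blood Cell Characteristics and
    Thrombectomy Recanalization Success
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for sex-stratified analysis of routine
    hematology-analyzer blood cell characteristics (BCCs) in relation to
    recanalization success of endovascular thrombectomy in acute ischemic
    stroke. Covers rule-based TICI grade extraction from radiology report
    text, FDR-corrected univariate sex comparisons, collinearity clustering
    of BCCs with Rand-index model selection, a from-scratch sparse PLS
    discriminant analysis with stability selection over repeated stratified
    cross-validation, dual-outcome (recanalization and stroke etiology)
    consistency mapping, and covariate-adjusted logistic models fitted by
    an in-house IRLS routine. A synthetic-cohort generator with planted
    ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    mclust,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
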