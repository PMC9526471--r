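Package: mtcseq
Title: Development and Blinded Validation of an RNA-Seq Medullary Thyroid
    Carcinoma Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for developing and blindly validating a
    rare-class RNA-sequencing classifier that distinguishes medullary thyroid
    carcinoma (MTC) from non-MTC thyroid nodules in fine-needle aspiration
    biopsies. Implements dual-cohort negative-binomial differential expression
    with Benjamini-Hochberg correction, eight rule-based candidate feature
    sets augmented with a mandatory gene cassette, repeated stratified
    cross-validated competition between linear support vector machines and
    elastic-net logistic regression, a four-criterion locked-model selection
    rule, exact-binomial validation statistics with an arcsine proportion
    power analysis, AJCC 8th-edition TNM staging of the validation cohort,
    and a synthetic count-data generator that emulates the study design so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
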