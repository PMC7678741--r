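Package: thromboSVM
Title: Exhaustive SVM Panel Search and Label-Free Quantification
    Statistics for Two-Group Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing label-free quantification (LFQ) protein
    tables from two-group cohorts, built around the exhaustive evaluation of
    small protein panels (up to trios) with a linear soft-margin
    support-vector machine scored by resubstitution accuracy. Includes
    MaxQuant-style proteinGroups parsing with leading-protein selection,
    missing-value filtering (commonly-detected and minimum-valid-fraction
    rules), per-protein Wilcoxon rank-sum and Welch/Student t statistics with
    volcano quantities, SVM analyses of clinical covariates alone or combined
    with protein panels, and a synthetic cohort generator with planted
    discriminative proteins and intensity-dependent missingness for
    ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
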