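Package: fgmi
Title: Fournier's Gangrene Mortality Index Scoring and Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Fournier's Gangrene Mortality Index (FGMI), a
    five-parameter point score (age, creatinine, albumin, lymphocyte
    percentage, neutrophil-to-lymphocyte ratio) predicting mortality in
    Fournier's gangrene, together with the Laboratory Risk Indicator for
    Necrotizing Fasciitis (LRINEC) score. Provides the complete validation
    toolkit used to assess such scores: empirical ROC curves with DeLong
    and Hanley-McNeil confidence intervals, cutoff sensitivity/specificity,
    odds ratios with Woolf confidence intervals, chi-square tests with
    Cohen's w and noncentral chi-square post-hoc power, Mann-Whitney U and
    Kruskal-Wallis tests, logistic regression with Hosmer-Lemeshow fit, and
    a synthetic two-group cohort generator calibrated from published
    quartile summaries via lognormal marginals and a Gaussian copula.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
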