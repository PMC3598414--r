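Package: delbank
Title: Item-Bank Construction for Delirium Screening with Item Response Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds reduced screening item banks for the four Confusion
    Assessment Method (CAM) features of delirium from dichotomous
    indicator-response data. Implements tetrachoric correlation estimation
    with estimability screening of locally dependent indicator pairs,
    permuted parallel analysis, exploratory/confirmatory/bifactor models on
    tetrachoric matrices with CFI and RMSEA fit indices, two-parameter
    logistic item response models by marginal maximum likelihood, expected a
    posteriori trait scoring, and information-targeted selection of the top
    indicators per dimension at the median trait level of feature-positive
    persons. Includes a synthetic-cohort generator emulating the statistical
    structure of a post-acute delirium screening sample.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
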