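Package: ectnet
Title: Multivariate Analysis of ECT-Induced Regional Volume Change and Electric-Field Dose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Placement-stratified principal component analysis of regional
    brain volume change after electroconvulsive therapy (ECT), together with
    a surrogate electric-field (EF) dose model, spatial-similarity testing of
    component loadings against a reference depression-network map with
    permutation inference by baseline reshuffling, and confounder-adjusted
    outcome regression. Ships a synthetic cohort generator with a planted
    two-factor volumetric model so that every stage of the pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
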