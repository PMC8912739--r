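Package: genriskeq
Title: Genetic Risk Equivalents for Gene-Environment Analyses with Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for case-control gene-environment analyses built around the
    genetic risk equivalent (GRE), a risk-communication metric that expresses
    the effect of an exposure as the polygenic-risk-score (PRS) percentile
    difference conferring the same disease risk. Provides an unweighted
    allele-count PRS builder with percentile and five-level risk-category
    assignment, adjusted logistic odds-ratio estimation with AIC-based
    forward-backward covariate selection, multiplicative interaction and
    joint-effect analyses, GRE point estimates with delta-method, Fieller and
    parametric-bootstrap confidence intervals, a full study pipeline producing
    descriptive, stratified, joint, site/stage-specific and subgroup report
    tables, and a synthetic case-control cohort generator with frequency
    matching for validating the whole analysis chain by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
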