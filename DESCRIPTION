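Package: sctsim
Title: Synthetic Control Arms and Trial Simulation for Spinal Cord Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for exploring synthetic (model-predicted) control arms in
    spinal cord injury trials. Provides the ISNCSCI segmental coordinate
    system with derived motor scores (UEMS, LEMS) and cohort inclusion
    filters; a configurable generator of EMSCI-like synthetic cohorts with
    severity-dependent sigmoidal segmental recovery; a benchmark of six
    recovery-prediction architectures (regularized linear regression, random
    forest, gradient-boosted trees, a 1-D convolutional network, an
    attention-based sequence-to-sequence model, and a graph network over the
    myotome chain) mapping acute assessments to recovery-phase motor score
    sequences; evaluation metrics restricted to segments below the
    neurological level of injury; a Monte-Carlo trial simulation framework
    comparing randomized and synthetic controls under covariate matching
    with tolerances; and single-arm versus two-arm sample-size machinery
    based on exact noncentral-t power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    zoo
Config/testthat/edition: 3
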