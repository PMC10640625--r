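Package: netreconf
Title: Rest-Task Brain Network Reconfiguration Efficiency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for rest-task functional connectivity (FC)
    similarity ("reconfiguration efficiency") in longitudinal two-arm
    intervention designs. Covers ROI-level fMRI denoising and motion
    scrubbing (framewise displacement and DVARS censoring with linear
    interpolation), canonical-HRF task-activation regression, Fisher-z FC
    matrices, network-level intra- and internetwork rest-task FC
    similarity, breath-counting-task and Five Facet Mindfulness
    Questionnaire scoring with behavioral exclusion rules, permutation
    inference for linear mixed models with random intercepts and slopes,
    Cliff's delta effect sizes, and a synthetic multi-subject study
    generator with exported ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
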