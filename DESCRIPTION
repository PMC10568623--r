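Package: strokenet
Title: EEG Functional-Network Prediction of Post-Stroke Cognitive Outcome
Version: 0.1.0
Authors@R: person("strokenet", "developers", role = c("aut", "cre"),
    email = "maintainers@strokenet.dev")
Description: A reproducible pipeline for predicting 3-month post-stroke
    cognitive status (standardized MoCA scores) from resting-state EEG.
    Covers sensor-level preprocessing (band-pass/notch filtering, common
    average referencing, epoch rejection), Welch spectral features over
    eight frequency bands with the classical power ratios, an sLORETA
    inverse solution onto 68 Desikan-Killiany cortical regions, imaginary
    coherence connectivity with proportional edge thresholding,
    graph-theoretic network attributes (global efficiency, characteristic
    path length, clustering coefficient, modularity), and a two-stage
    machine-learning procedure: lesion-laterality classification followed
    by group-specific correlation/importance feature selection and
    leave-one-out regression. A synthetic-cohort generator with planted
    ground truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
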