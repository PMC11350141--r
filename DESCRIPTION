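Package: mcimark
Title: Neurovascular, Connectivity, and Extracellular-Vesicle Markers of Mild
    Cognitive Impairment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end analysis pipeline for multimodal biomarkers of mild
    cognitive impairment (MCI). Implements channel-wise general linear model
    (GLM) estimation of task-evoked neurovascular coupling from dual-wavelength
    functional near-infrared spectroscopy (fNIRS) recordings via the modified
    Beer-Lambert law, graph-theoretical functional connectivity on
    surrogate-thresholded total-hemoglobin correlation networks, signal
    detection (d-prime) scoring of n-back working-memory performance, gating
    and quantification of cerebrovascular endothelial extracellular vesicles
    from small-particle flow-cytometry event tables, the accompanying
    statistics layer (Mann-Whitney, mixed two-way ANOVA with Bonferroni post
    hocs, ROUT outlier screening, Benjamini-Hochberg FDR, Cohen's d), and a
    leave-one-out cross-validated random-forest classification protocol.
    Ships a synthetic-cohort generator with configurable planted group
    effects so every stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
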