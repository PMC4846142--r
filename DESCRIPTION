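Package: tilapiaann
Title: Non-Lethal Pansteatitis Classification from Fish Blood Chemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening pansteatitis (inflammatory disease of
    adipose tissue) in wild fish from a benchtop blood-chemistry panel
    without necropsy. Implements quality-control arithmetic for replicate
    panels and certified reference materials (relative standard deviation,
    symmetric percent difference, derived globulin), an assumption-driven
    univariate comparison battery with sexual-dimorphism stratification
    (Shapiro-Wilk and Levene gates selecting t-tests or Mann-Whitney U),
    a feed-forward neural-network ensemble trained on resampled 70/30
    splits with per-variable sensitivity ranking, ROC/AUC evaluation of
    pooled cross-validation predictions, top-variable re-modelling, and
    clamped two-variable response and sampling-adequacy surfaces. A
    synthetic cohort generator reproduces the group structure of the
    source study so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
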