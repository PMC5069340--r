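Package: cfaer
Title: Automated Detection and Cross-System Harmonization of Complex
    Fractionated Atrial Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-implementations of the two automated complex-fractionated
    atrial electrogram (CFAE) detectors embedded in clinical electroanatomical
    mapping systems (the NavX CFE-Mean/CFE-SD deflection detector and the
    CARTO ICL/ACI/SCI complex-interval detector), together with the
    resampled train/validation ROC pipeline that revises their detection
    thresholds so the two systems classify fractionation concordantly.
    Includes a synthetic bipolar atrial electrogram generator with planted
    ground truth, a nonparametric concordance toolkit (ROC with
    closest-to-corner optimum, Cohen's kappa, Spearman, Yates chi-square,
    Mann-Whitney, Friedman with Dunn's correction), and plain-text signal
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
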