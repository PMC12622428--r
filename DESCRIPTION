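Package: avidex
Title: Avidity-Based Exosome Capture Analysis: AFM Force Spectroscopy Scoring and Biomarker Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for avidity-based capture of PD-L1 positive
    exosomes. Scores atomic force microscopy force-distance retraction curves
    for molecular rupture events at a fixed force threshold, classifies
    single versus multiple (multivalent) binding, and computes the maximum
    adhesion force and the adhesion energy per curve together with grid-level
    summaries and heatmaps. Includes a calibrated synthetic force-curve
    generator for four capture-surface presets, the clinical biomarker
    statistics used to evaluate captured exosomes as an immunotherapy
    biomarker (Kolmogorov-Smirnov gated two-group tests, empirical ROC/AUC,
    Kaplan-Meier, log-rank, univariate Cox regression and Schoenfeld power,
    all implemented from first principles), and log-linear ellipsometric
    biosensor calibration with a three-sigma limit of detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
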