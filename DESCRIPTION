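Package: rtbridge
Title: Retention Time Index Projection and Prediction Across Liquid
    Chromatography Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing retention behaviour across reversed-phase
    liquid chromatography systems in non-target screening. Converts retention
    times to pairwise retention time indices anchored on shared calibrants,
    transfers indices between systems with penalized-spline generalized
    additive models, quantifies retention-order similarity (Spearman) and
    peak spacing along the elution program, trains gradient-boosted
    retention-time prediction models with calibrant-based recalibration onto
    a target system's index scale, and compares projection against prediction
    per system pair with F-tests on the error variances. Includes a
    multi-system chromatography simulator with known ground truth (monotone
    gradient warps, isocratic plateaus, additive-dependent shifts of
    ionizable compounds, detection dropout) so every stage can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    grDevices,
    graphics,
    jsonlite,
    mgcv,
    stats,
    utils,
    xgboost
Suggests:
    ChemmineOB,
    ChemmineR,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
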