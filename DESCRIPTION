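Package: surgaze
Title: Surgical Eye-Tracking Analytics for Heads-Up Display Cataract Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for surgeon gaze behavior recorded during
    simulated cataract surgery on a 3-D heads-up display: dispersion-based
    (I-DT) fixation, saccade and blink detection; area-of-interest gaze
    distribution; pixel-mask coverage quantification of the operative field;
    capsulorhexis tear geometry (tear angle relative to the forceps, tear
    length as a fraction of the capsulorhexis model, initiation distance and
    isoperimetric circularity); and group-level inference (one-way ANOVA,
    Tukey HSD and Pearson correlation) computable directly from published
    summary statistics. A synthetic-data generator emulates gaze streams,
    surfaces, mask images and tear annotations for expertise profiles with
    ground-truth event logs, so every stage is testable without recordings.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
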