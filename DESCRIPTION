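Package: iolpower
Title: Personalized Intraocular Lens Power Calculation with an Ensemble
    Effective-Lens-Position Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thin-lens vergence optics for pseudophakic intraocular lens (IOL)
    power calculation, the four classical third-generation formulae (Haigis,
    Hoffer Q, Holladay I, SRK/T) with per-lens constant optimization, and an
    ensemble-regression predictor of the effective lens position (ELP) fitted
    on back-calculated post-operative data.  Includes a Monte-Carlo
    cross-validation benchmark with axial-length stratification, the
    non-parametric comparison battery used in refractive-outcome studies
    (Wilcoxon, Friedman, Cochran's Q, McNemar), and a calibrated synthetic
    cataract-surgery cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    xgboost,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
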