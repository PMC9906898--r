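Package: thalscreen
Title: Discriminant Indices for Separating Thalassemia Trait from Iron
    Deficiency Anemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for screening thalassemia trait (TT) against iron
    deficiency anemia (IDA) from complete-blood-count (CBC) parameters in
    first-trimester pregnancy. Ships a machine-readable registry of 44
    published discriminant formulas with their comparators and cutoffs
    (Mentzer, Shine and Lal, Green and King, the log-based XS-1 family,
    and others), a diagnostic-performance engine (confusion counts, exact
    Clopper-Pearson confidence intervals, ROC curves, trapezoid/DeLong
    AUC, Youden-index optimal cutpoints, rankable cohort reports), the
    study-style eligibility cascade with TT/IDA group assignment, and a
    seedable synthetic CBC cohort generator calibrated to published group
    means and standard deviations, so the whole evaluation runs without
    patient data. A command-line interface covers single-record
    screening, batch scoring, cohort evaluation, and simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
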