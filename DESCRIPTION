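Package: nodulerisk
Title: Risk Stratification of Screen-Detected Pulmonary Nodules and
    Comparison of Scoring Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores screen-detected pulmonary nodules on baseline low-dose
    CT under three management systems: the PanCan (Brock) logistic
    malignancy-risk model, the ACR Lung-RADS version 1.0 assessment
    categories, and the NCCN version 1.2016 nodule-management categories.
    Each system can be driven by any of three interchangeable nodule size
    definitions (longest axial diameter, volumetric mean diameter, mean of
    longest and perpendicular axial diameters).  Provides per-participant
    risk-dominant nodule selection, ROC analysis with midrank AUC, paired
    DeLong tests with Bonferroni correction for comparing systems and size
    definitions, demographics tables, cohort CSV/TSV input and output, and
    a calibrated synthetic case-control cohort generator so the full
    pipeline can be exercised without access to screening-trial data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    data.table,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
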