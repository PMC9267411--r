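Package: octprog
Title: Prognosis Classification for Macular Edema in Branch Retinal Vein
    Occlusion from OCT Layer-Brightness Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline that classifies the visual-acuity
    prognosis of eyes with macular edema secondary to branch retinal vein
    occlusion during the maintenance phase of anti-VEGF therapy.  Handcrafted
    brightness features (continuity, clarity, and outer-segment area of the
    external limiting membrane and ellipsoid zone) are computed from trimmed
    OCT B-scans with per-column layer annotations; candidate explanatory
    variables are screened with exact Fisher r-by-c, two-sample
    Kolmogorov-Smirnov, and Wilcoxon signed-rank tests followed by an
    iterative variance-inflation-factor elimination loop; a class-weighted
    L2-regularized logistic classifier is fitted by quasi-Newton
    minimization; and a two-stage repeated stratified evaluation yields AUC
    and coefficient-contribution interval estimates.  A calibrated synthetic
    cohort generator renders OCT-like B-scans and clinical covariates with
    group-conditional structure so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
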