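Package: tmaboost
Title: Weakly Supervised Treatment-Effect Prediction from Tissue Microarray Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for weakly supervised analysis of
    immunohistochemistry-stained tissue microarray (TMA) whole-slide images.
    Provides a multiresolution pyramid data model with forward/backward
    coordinate mapping, classical and cascade-orchestrated TMA core
    detection, tumorlike-tissue tile selection from per-pixel class maps,
    a boosting training loop with attention-based instance reweighting,
    focusing sampling and boosted data augmentation, core-level
    treatment-effectiveness prediction with pluggable classifier backends,
    derivative-based model selection with early stopping, classification
    and survival-linked evaluation (ROC/AUC, Kaplan-Meier, log-rank, Cox),
    and a seeded synthetic TMA generator so the whole pipeline is testable
    without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    survival,
    stats,
    jsonlite,
    png,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    tiff
Config/testthat/edition: 3
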