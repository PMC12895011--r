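Package: attnmil
Title: Attention-Based Multiple Instance Learning for Whole-Slide Recurrence-Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits gated attention-based multiple instance learning (ABMIL) models on
    bags of whole-slide-image patch embeddings to classify or regress PAM50 ROR-P
    recurrence-risk scores, with a participant-stratified cross-validation harness,
    softmax-ensemble inference for external cohorts, discrimination and survival
    evaluation (ROC AUC with DeLong comparison, Pearson correlation with Meng's z,
    concordance index with a correlated C-index comparison, univariable Cox,
    log-rank, Youden threshold selection), and a perturbation-based interpretability
    suite testing tissue-region necessity and sufficiency and greedily searching for
    minimal risk-flipping patch sets. A synthetic-cohort generator with planted
    signal and exponential recurrence outcomes makes the full pipeline testable
    without access-controlled slide data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pROC,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
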