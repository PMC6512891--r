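Package: affectfar
Title: Facial Action Recognition Features for Psychiatric Affect Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for analyzing multi-rater affect annotation of face
    videos with facial-action-recognition features. Normalizes face frames by
    landmark alignment, records grid-cell mean gray-level intensity series,
    derives three mid-level per-video features (averaged expression scores,
    dominating-label transitions, motion standard deviation) and their
    concatenations, predicts each rater's quality/range/subtype labels with a
    one-vs-all linear SVM under leave-one-out evaluation, and computes
    inter-rater percent-agreement matrices and multinomial
    logistic-regression likelihood-ratio tests per feature kind and facial
    region. Includes a synthetic cohort generator emulating videotaped
    psychiatric interviews with a confusion-matrix rater model, so the whole
    analysis is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    nnet,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
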