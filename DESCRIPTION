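Package: mmshap
Title: Multimodal Shapley Explanations for Text-Tabular Clinical Mortality Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shapley-value explanations for classifiers that mix free-text
    clinical narratives with tabular electronic-health-record features, using
    modality-specific masking: absent word-pieces are replaced by a [MASK]
    token while absent tabular features are integrated over a background
    dataset. Ships the five text-tabular combination architectures
    (All-Text serialisation, weighted ensembles, stack ensemble), a
    case-control mortality cohort builder for veterinary consultation
    records (regex flagging, teacher-student label propagation,
    preceding-consultation case assembly), token-to-feature importance
    aggregation, Kendall rank-stability analytics, and a seeded synthetic
    EHR cohort generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
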