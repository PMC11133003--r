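Package: spinr
Title: Sex-Specific Pathway-Masked Neural Networks for Sexual Dimorphism Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint modelling of male and female gene expression profiles with a
    pathway-masked neural network whose first layer is routed by sex. The model
    predicts survival via a Cox partial-likelihood prognostic index or binary
    disease risk via a sigmoid head, learns sparse hidden connectivity by
    validation-selected magnitude pruning, and is interpreted globally
    (sex-shared versus sex-specific genes and pathways with rank tests and
    false discovery rate control) and locally (Shapley-value pathway
    attributions, including cross-sex counterfactual routing). Includes a
    synthetic-data generator with planted sex-shared, sex-specific and
    opposite-direction pathway effects, evaluation metrics (Harrell's
    concordance index, AUC, five-group disease-ratio stratification), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
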