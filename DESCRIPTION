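Package: adralert
Title: Adverse Drug Reaction Prediction from SMILES with a Chemical
    Language Encoder, CNN Head and Structural-Alert Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts binary adverse-drug-reaction risk (QT prolongation,
    teratogenicity, rhabdomyolysis and similar endpoints) from canonical
    SMILES. Molecules are encoded by a transformer chemical language model
    with rotary positional embeddings and linear attention (a small
    self-contained reference encoder ships with the package; a pre-trained
    checkpoint can be adapted), classified by a two-convolution CNN head,
    and evaluated by leakage-safe stratified group fivefold cross-validation
    over nine binary-classification metrics. Attention maps are average-
    pooled into per-atom importance scores and matched against a SMARTS
    structural-alert catalog. A synthetic planted-alert data generator makes
    the whole pipeline testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
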