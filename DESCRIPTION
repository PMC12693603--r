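Package: odorgraph
Title: Graph Neural Networks and Descriptor Baselines for Multi-Label
    Molecular Odor Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for quantitative
    structure-odor relationship (QSOR) modelling. Converts SMILES to
    molecular graphs with a fixed 25-dimensional atom and 6-dimensional
    bond featurization, trains graph neural networks (GCN, GAT, NNConv)
    with imbalance-aware losses (plain, inverse-frequency weighted and
    focal binary cross-entropy), and compares them against six descriptor
    based learners under three feature-processing strategies (tiered
    imputation/IQR clipping/standardization, four-stage feature
    selection, PCA/kernel-PCA reduction). Includes per-label decision
    threshold calibration, multi-label evaluation metrics, two-method
    applicability-domain assessment (ECFP4 Tanimoto and embedding-space
    distance), fragment-level model interpretation via gradient and
    attention attribution with SMARTS functional-group mapping, and a
    synthetic molecule generator with planted structure-odor rules for
    fully self-contained validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    stats,
    utils,
    jsonlite,
    ranger,
    e1071,
    xgboost,
    nnet,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
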