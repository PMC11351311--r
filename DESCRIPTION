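Package: fedchain
Title: Blockchain-Secured Federated Learning Simulation for Clinical Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained, desk-scale simulation of privacy-preserving
    federated learning for diabetes risk prediction, secured by a permissioned
    hash-chained ledger with smart-contract semantics. Provides a synthetic
    electronic-health-record cohort generator with a known logistic outcome
    model, a preprocessing pipeline (imputation, encoding, scaling,
    undersampling, client partitioning), Ed25519-authenticated transactions
    with replay protection, an append-only block chain with a local
    content-addressed off-chain store, contract state machines for role
    registration, consent management, validated model-update submission and
    incentive accounting, a federated training loop for gradient-boosted tree
    classifiers aggregated by prediction distillation, scripted adversarial
    scenarios, and communication-overhead accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    openssl,
    R6,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
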