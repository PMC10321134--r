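Package: oedl
Title: Optimized Stacked Ensembles of Deep Learners for Multiclass Clinical Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for three-class prognosis modelling from fused clinical and
    radiomics-style tabular data. Implements a leakage-safe feature-fusion
    pipeline (Monte Carlo multiple imputation, variance filtering, one-hot
    encoding, z-score standardization, dual gradient-boosting importance
    selection with Pearson correlation pruning), hybrid SMOTE+ENN class
    balancing, three deep base learners (feed-forward network, single-step
    LSTM, deep belief network pretrained by contrastive divergence) under a
    common fit/predict-probability contract, stacked generalization with
    out-of-fold meta-features and a random-forest meta-learner, a chaotic-map
    swarm metaheuristic (big bang optimization algorithm, BBOA) for
    hidden-layer architecture search, macro-averaged one-vs-rest multiclass
    evaluation, and a seed-reproducible synthetic cohort generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost,
    randomForest,
    rpart,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
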