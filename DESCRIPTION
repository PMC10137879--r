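Package: cohortgcn
Title: Semi-Supervised Graph Convolutional Networks on Population Graphs of Brain Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds weighted population (cohort) graphs from pairwise similarity of
    vectorized brain structural connectomes and trains semi-supervised graph
    convolutional network (GCN) classifiers on them for binary clinical outcome
    prediction. Includes the renormalized first-order propagation operator,
    masked transductive training with inverse-frequency class-weighted
    cross-entropy and Adam, repeated stratified cross-validation with
    supervised baselines (regularized logistic regression, ridge classifier,
    linear and RBF support vector machines, a feed-forward network), a
    loss-weighting ablation, and a synthetic-cohort generator emulating a
    partially labeled preterm-infant connectome cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
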