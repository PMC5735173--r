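Package: dtiBoost
Title: Drug-Target Interaction Prediction from Evolutionary and
    Structural Protein Features with Boosted Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-target interactions from a bipartite
    drug-protein network treated as a heavily imbalanced binary
    classification problem. Target proteins are encoded by PSSM-bigram
    evolutionary features and by structural features derived from
    predicted secondary structure, accessible surface area, backbone
    torsion angles and structural probabilities; drugs by 881-bit
    PubChem substructure fingerprints. Class imbalance is handled by
    random or cluster-based under-sampling of the majority
    (non-interacting) class applied to training folds only,
    classification by discrete AdaBoost over depth-limited decision
    trees, and evaluation by ROC/precision-recall areas under repeated
    stratified cross-validation. Includes parsers for PSI-BLAST ASCII
    PSSM and SPIDER2 SPD files, a synthetic-fixture generator with
    plantable signal and configurable imbalance ratio, and a ranking
    utility that proposes new interactions from high-scoring negative
    pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    rpart,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    rcdk
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'dtiBoost-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'balancing.R'
    'boosting.R'
    'dataset.R'
    'drugFeatures.R'
    'evaluation.R'
    'fixtures.R'
    'io.R'
    'pipeline.R'
    'proteinFeatures.R'
    'tree.R'
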