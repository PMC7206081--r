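Package: zipthread
Title: Steric-Zipper Threading for Peptide Amyloidogenicity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Threads short peptides (4-10 residues) onto idealized
    steric-zipper templates representing the experimentally confirmed
    structural classes of amyloid crystals, scores the threaded models
    with a trainable distance-dependent statistical potential and a
    decomposed coarse-grained energy function, and classifies peptides
    as amyloid-forming or not with interpretable machine-learning
    models (L1-regularized logistic regression, support vector
    machines, random forests).  Includes structural-class assignment
    by minimum energy, feature-importance analysis with an all-relevant
    Boruta selector, and a synthetic-data generator for end-to-end
    validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    glmnet,
    e1071,
    ranger,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
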