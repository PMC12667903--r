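Package: cpscan
Title: Circular-Permutation-Invariant Protein Structure Embedding and Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects protein pairs related by circular permutation. Represents
    backbones as Calpha contact graphs, learns structure embeddings with an
    E(3)-invariant graph neural network trained by supervised contrastive loss
    under synthetic-circular-permutation (synCP) augmentation, and verifies
    candidate pairs with a CP-aware duplicate-and-align TM-score aligner. A
    dual-model filter (one CP-sensitive encoder, one CP-invariant encoder)
    surfaces pairs whose similarity is unlocked by allowing the chain to wrap
    around, and a synthetic-backbone generator provides labeled families,
    planted circular permutants and decoys so the whole pipeline runs without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
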