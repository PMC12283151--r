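Package: songform
Title: Form-Function Analysis of Cross-Cultural Song Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing corpora of vocal music annotated with
    behavioral context, languoid (glottocode) and geographic origin. Provides
    a class-balanced bootstrap ensemble of L1-penalised multinomial
    classifiers with modal-vote aggregation, confusion and d-prime reporting
    and permutation significance testing; Bayesian hierarchical variance
    partitioning of acoustic features into behavioral-context, culture,
    phylogenetic and geographic components via intra-class correlations, with
    Brownian tree covariances and exponential geographic Gaussian-process
    kernels; and a synthetic-corpus generator with known ground-truth
    variance components for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    glmnet,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rjags,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
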