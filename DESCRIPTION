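Package: brass
Title: Permutation Testing for Binary Traits in Structured Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates permutation-style null replicates of a correlated
    binary trait in samples with population structure and relatedness, by
    fitting a quasi-likelihood null model with a genetic relatedness matrix,
    decorrelating the phenotypic residuals to second-order exchangeability,
    permuting, and back-transforming. Includes six comparator resampling
    methods (naive residual permutation, MVNpermute, a penalized
    quasi-likelihood logistic mixed model sampler, and binarized variants),
    a retrospective quasi-score association test for single markers, GRM
    construction with principal-component adjustment and
    leave-one-chromosome-out support, a two-subpopulation Balding-Nichols
    pedigree simulator with calibrated logistic and liability-threshold
    trait models, and a simulation pipeline for evaluating the type 1 error
    of empirical genome-wide significance thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
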