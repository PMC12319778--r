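Package: plsperm
Title: Permutation, Stability, and Bootstrap Inference for Partial Least
    Squares Correlation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the partial least squares (PLS) correlation of two
    data blocks measured on the same observations (e.g. brain and
    behavioural matrices), together with the full family of
    permutation-based significance tests in use for it: the unrotated test
    and three variants that apply an orthogonal Procrustes rotation to the
    permuted singular vectors (behaviour side, brain side, or both) before
    scoring the null. Complements significance with latent-variable
    strength (covariance explained), split-half stability, and bootstrap
    feature-weight reliability. Includes a generative model for two-block
    multivariate-normal data with a single latent effect of specified
    canonical correlation, plus simulation sweeps over sample size, effect
    strength, and additive noise for studying the error rates and
    sensitivity of each permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: StatisticalMethod, DimensionReduction, MultipleComparison
RoxygenNote: 7.3.3
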