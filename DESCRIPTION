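Package: fsadim
Title: Manifold-Adaptive Intrinsic Dimension Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Intrinsic dimension estimation for point clouds and time-delay
    embedded time series with the two-scale nearest-neighbor
    (Farahmand-Szepesvari-Audibert) local estimator. Provides the median
    aggregate (mFSA), the exact distribution theory of the local estimates
    under locally uniform density (pdf, cdf, beta transform, sampling
    distribution and standard error of the median), a maximum-likelihood
    variant, and a calibrated exponential bias correction (cmFSA) fitted on
    uniform hypercube datasets to absorb finite-sample and edge effects.
    Includes exact k-nearest-neighbor search under hard or periodic
    (minimum-image) boundary conventions, synthetic manifold samplers, a
    coupled logistic-map simulator, delay embedding, and benchmark metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
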