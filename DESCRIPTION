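Package: trajmix
Title: Bayesian Longitudinal Trajectory Clustering with Mixtures of
    Multivariate Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Groups subjects of a longitudinal cohort by their multi-region
    trajectory patterns using a fully Bayesian finite mixture of multivariate
    linear mixed models fit by Gibbs sampling with conjugate full
    conditionals. Supports control-referenced z-standardization of regional
    measurements, soft clustering with posterior allocation probabilities,
    classification uncertainty via highest-posterior-density intervals,
    outlier-cluster detection, hybrid model selection across cluster counts
    and initializations, multidimensional scaling of the probability matrix,
    cluster fitted-value maps, and a synthetic cohort simulator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    mclust
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
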