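Package: orthomds
Title: Robust Multidimensional Scaling with Orthogonal Outlier Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects orthogonal outliers in a pairwise dissimilarity matrix
    and corrects their distances before multidimensional scaling. The
    dimension of the main data subspace is estimated from the heights of
    randomly sampled simplices, computed from distances alone through
    Cayley-Menger determinants; points whose median height at the estimated
    dimension stands out are flagged, the dimension estimate is debiased
    for the measured outlier fraction, and the outliers are projected onto
    the principal subspace fitted through the regular points, yielding a
    corrected distance matrix suitable for low-dimensional embedding.
    Includes synthetic-data generators with planted outliers, evaluation
    utilities (Shepard pairs, dimension-bias sweeps) and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
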