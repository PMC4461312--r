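Package: commsize
Title: Sample-Size Adequacy for Multivariate Abundance-Based Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to ask how many individuals per sample are enough for
    multivariate community ecology. Communities are simulated along an
    environmental gradient (Gaussian taxon response curves) or built with
    controlled Pielou evenness; every sample is then rarefied without
    replacement to fixed proportions of its original size, and each
    subsampled matrix is compared with the complete one by a Mantel test on
    Bray-Curtis dissimilarities and by Procrustes/PROTEST concordance of
    two-dimensional NMDS ordinations. Goodness-of-fit curves against median
    subsample size are aggregated and a two-segment piecewise-linear fit
    locates the sample size above which results plateau.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
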