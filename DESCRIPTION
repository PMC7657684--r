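Package: steamchem
Title: NIR Chemometrics for In-Line Monitoring of Herbal Steaming Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multivariate calibration toolkit for near-infrared (NIR)
    process monitoring of steamed Gastrodiae rhizoma (Tianma). Provides
    spectral preprocessing (multiplicative scatter correction, standard
    normal variate, Savitzky-Golay smoothing and derivatives), PCA and
    Mahalanobis-distance outlier screening, Kennard-Stone sample-set
    partitioning, calibration by stepwise multiple linear regression,
    NIPALS partial least squares, synergy-interval PLS variable selection
    and principal component regression, leave-one-out latent-variable
    selection, and the standard NIR validation statistics (RMSEC, RMSECV,
    RMSEP, R2, RPD, RSEP) together with paired t and F agreement tests.
    A seeded generator of steaming-process spectra with paired reference
    values supports end-to-end validation of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'calibration.R'
    'evaluation.R'
    'interval-pls.R'
    'spectra-io.R'
    'sample-selection.R'
    'preprocessing.R'
    'synthetic-data.R'
    'pipeline.R'
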