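Package: slowwave
Title: Spatial LFP Correlation Structure and Slow-Wave Sleep Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the spatial correlation structure of
    multichannel local field potential (LFP) recordings from planar
    microelectrode arrays during sleep, and for relating that structure to
    sleep state. Computes per-epoch Fisher z-transformed correlation-by-
    distance functions on Utah-array geometries, fits exponential, power-law,
    Gaussian and linear spatial decay models by count-weighted regression,
    stages epochs as slow-wave sleep, REM/awake or null from delta and gamma
    band power of a virtual LFP via Gaussian-mixture clustering, and
    quantifies the coupling between spatial decay parameters and sleep state
    (Type-2 regression, d-prime, coefficients of variation with bootstrap
    confidence intervals). Includes a synthetic multichannel LFP generator
    with known spatial covariance, state-dependent band power, alternating
    sleep-state epochs and wireless-dropout artifacts, used as ground truth
    throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    mclust,
    minpack.lm,
    jsonlite,
    arrow
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'recording-methods.R'
    'filters.R'
    'preprocess.R'
    'layout.R'
    'correlation.R'
    'decay.R'
    'synthetic.R'
    'io.R'
    'threshold.R'
    'staging.R'
    'state-analysis.R'
    'pipeline.R'
    'slowwave-package.R'
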