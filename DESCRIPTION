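Package: probencode
Title: Versatile Encoding and Decoding of Probability and Confidence in
    Event Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how neural time series encode the hidden
    probability of events in a changing environment.  Implements a Bayesian
    change-point ideal observer for binary sequences (grid filtering of a
    hidden Bernoulli parameter under a constant hazard), basis-function
    ("versatile") voxelwise encoding models with HRF convolution, ridge
    fitting and a cross-validated z-R2 score standardized against a
    generated-sequence null, tuning-curve shape metrics (non-monotonicity,
    nonlinearity, prominence-based peak counts), correlation-distance
    nearest-pattern decoding of probability and confidence bins with
    representational dissimilarity (RDM) model regression, and a synthetic
    BOLD generator for model-recovery simulations at configurable scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    RNifti
Config/testthat/edition: 3
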