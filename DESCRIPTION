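Package: urefs
Title: Unipolar EEG References and Estimation of Scalp Potentials at Infinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the family of EEG unipolar references (recording
    reference, linked mastoids, average reference and the reference
    electrode standardization technique, REST) viewed as rank-one
    transformations T = I - 1 f' of the unobservable potentials referenced
    at infinity.  Provides a three-concentric-sphere analytic forward
    model, construction and application of unipolar reference operators,
    the REST standardization matrix and its unipolar form, regularized
    REST (rREST) with generalized cross-validation, the constrained
    best-linear-unbiased and maximum-likelihood estimators of the
    infinity-referenced potentials, Bayesian MAP estimators under IID
    potential or IID source priors, lead-field based interpolation of
    missing channels, and a synthetic-recording simulator for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
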