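Package: nirsaware
Title: Awareness Detection from fNIRS Recordings via Riemannian
    Covariance Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects command-following (behavioural responsiveness) in
    functional near-infrared spectroscopy (fNIRS) recordings of a
    motor-speech imagery paradigm.  Implements the full chain from raw
    two-wavelength intensities through optical-density conversion,
    temporal derivative distribution repair, short-channel regression,
    the modified Beer-Lambert law, band-pass filtering and epoching, to
    trial-wise decoding of IMAGERY versus NO-IMAGERY using
    prototype-augmented, xDAWN-filtered, OAS-shrunk covariance matrices
    classified in the tangent space of the SPD manifold.  A permutation
    test on the cross-validated accuracy, taken over HbO, HbR and
    combined feature sets, yields a RESPONSIVE/UNRESPONSIVE diagnosis
    per dataset.  A forward simulator generates synthetic recordings
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    rlang,
    signal,
    jsonlite,
    stats,
    utils,
    tibble,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
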