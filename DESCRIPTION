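Package: twistretch
Title: Twist-Stretch Coupling of DNA and RNA Duplexes from Helical
    Coordinate Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Harmonic elasticity analysis of double-stranded DNA and RNA in
    helical base-pair axis coordinates. Generates Gaussian ensembles of
    helical parameters with DNA-like and RNA-like presets, infers the 2x2
    stiffness matrix of total twist and duplex length from coordinate
    covariances, and reports the twist-stretch coupling coefficients by the
    covariance route, by binned linear regression of rise on twist, and by a
    torque-restrained twist scan. A rigid base-pair geometry engine builds
    three-dimensional duplex models from helical parameters, inverts the
    construction, and measures extension, helix radius and groove-width
    proxies, exposing the geometric mechanism that couples twist, rise,
    inclination and x-displacement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'utils.R'
    'ensemble_spec.R'
    'sample_ensemble.R'
    'elasticity.R'
    'fit.R'
    'torque_scan.R'
    'binning.R'
    'geometry.R'
    'io.R'
    'twistretch-package.R'
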