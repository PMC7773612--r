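Package: menirmap
Title: Chemometric Calibration and Spatial Mapping of Tissue Composition from
    Near-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete diffuse-reflectance near-infrared (NIR) chemometrics
    pipeline for calibrating tissue constituent contents (water, uronic acid,
    hydroxyproline as percent of wet weight) against spectra and mapping them
    over a sparse measurement grid. Provides spectral preprocessing (range
    cropping, SNV/RNV/MSC scatter correction, Savitzky-Golay
    smoothing/derivatives) with a combinatorial configuration search, NIPALS
    partial least squares regression with Monte Carlo cross-validation and
    Monte Carlo outlier screening, five wavelength-selection algorithms (UVE,
    CARS, random frog, MWPLS, IRIV), sparse-grid neighbour-mean imputation
    with bilinear map interpolation, and a synthetic phantom generator that
    emulates the statistical structure of meniscus NIR measurements so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
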