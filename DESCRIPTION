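Package: hsimcr
Title: Multiset MCR-ALS Unmixing of FTIR Hyperspectral Images of Wood Sections
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipelines", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to resolve hyperspectral mid-infrared absorbance images of
    plant tissue into constituent spectra and distribution maps. Implements
    spectral-window truncation, asymmetric least squares (AsLS) baseline and
    scatter correction, Savitzky-Golay smoothing for point spectra, row-wise
    multiset augmentation of unfolded images, SIMPLISMA purest-pixel initial
    estimates, and multivariate curve resolution by alternating non-negative
    least squares (MCR-ALS) with spectra normalization and
    correspondence-of-species constraints. Includes a synthetic-data generator
    that emulates annual-ring series of wood cross sections (ray, cell wall,
    cell corner, lumen geometry) with known ground truth, band-intensity
    tracking across rings, and localization of the sapwood-to-heartwood
    transition zone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
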