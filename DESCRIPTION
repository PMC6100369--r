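Package: nirquant
Title: Near-Infrared Diffuse Reflectance Quantitation of Herbal Saponins by
    Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate calibration workflow for quantifying a triterpene
    saponin (Shengmaxinside I) in honey-fried Rhizoma Cimicifugae from
    near-infrared diffuse reflectance spectra. Provides an S4 container for
    spectral matrices built on SummarizedExperiment, the standard NIR
    pretreatment operators (standard normal variate, multiplicative scatter
    correction, finite-difference and Savitzky-Golay derivatives, Norris
    gap-segment derivatives), NIPALS PLS1 regression with leave-one-out
    cross-validation and PRESS-based factor selection, wavenumber-window and
    pretreatment grid search ranked by RMSECV, evaporative light scattering
    detector (ELSD) log-log calibration against an embedded reference table,
    and a synthetic spectrum generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
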