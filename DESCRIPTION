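Package: robnir
Title: Robust Sparse Partial Least Squares Calibration for Vis-NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A calibration pipeline for predicting fruit soluble-solids
    content (SSC, degrees Brix) from visible/near-infrared reflectance
    spectra. Provides spectral preprocessing (Savitzky-Golay and
    Norris-Williams smoothing, continuous-wavelet derivatives,
    multiplicative scatter correction, variable sorting for
    normalization), SPXY calibration/prediction set partitioning,
    Monte-Carlo uninformative variable elimination (MCUVE) wavelength
    selection, and three latent-variable regression estimators: classical
    PLSR (NIPALS), sparse PLSR with soft-thresholded weight vectors, and
    sparse partial robust M regression (SPRMR) fitted by iteratively
    reweighted least squares with case weights that flag vertical
    outliers and leverage points. Includes RPD/RER model evaluation, a
    white-Gaussian-noise injection harness for assessing robustness of
    the estimators at controlled signal-to-noise ratios, and a seeded
    synthetic-spectra generator emulating static and online acquisition
    of fruit reflectance spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
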