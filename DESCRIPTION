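Package: hsical
Title: Calibration of Intraoperative Hyperspectral Imaging Setups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reflectance calibration chain for intraoperative hyperspectral
    imaging with either a microscope filter-wheel setup (narrowband
    illumination, panchromatic sensor) or mosaic snapshot cameras (4x4 and
    5x5 multispectral filter arrays). Implements flat-field/vignetting
    correction, dark-current subtraction and one-point white-reference
    conversion to reflectance, signal-to-noise estimation from dark-frame
    stacks, spectral crosstalk correction by a regularized deconvolution
    matrix, normalized cross-correlation band registration and assembly of a
    joint 41-band hypercube, scalar intensity (systematic-shift) correction
    fitted against a 24-tile reference chart, CIE-based RGB reconstruction,
    and PCA minor-component band enhancement for tissue visualization. A
    synthetic forward model of both camera setups (illumination spectra,
    Gaussian band responses with secondary peaks, vignetting, dark current,
    read and shot noise, saturation) provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
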