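Package: berrytrace
Title: Geographic Origin Tracing from NIR Hyperspectral Images of Berries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for tracing the geographic origin of
    berry samples from near-infrared hyperspectral image cubes. Covers
    white/dark reflectance calibration, background masking and object
    segmentation, pixel-wise and object-wise principal component analysis,
    spectral preprocessing (moving-average and Savitzky-Golay smoothing and
    derivatives), characteristic-wavelength selection from PCA loadings and
    second-derivative spectra, Kennard-Stone sample-set partitioning, and
    three discriminant models (support vector machine, exact-design radial
    basis function network, extreme learning machine) with their grid
    searches and macro-averaged evaluation. A seeded synthetic-scene
    generator emulating berry reflectance spectra with NIR absorption bands
    makes every stage runnable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    signal,
    e1071,
    EBImage,
    MASS
Suggests:
    testthat (>= 3.0.0),
    readxl,
    jsonlite
Config/testthat/edition: 3
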