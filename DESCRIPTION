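Package: oatpipe
Title: Optoacoustic Tomography Processing for Hybrid MR-Optoacoustic Neuroimaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and processing of volumetric optoacoustic tomography
    (OAT) data acquired concurrently with MRI. Provides a seeded synthetic-data
    generator (hemispherical detection arrays, analytic N-wave forward model,
    paradigm-driven hemodynamics, MRI interference bursts, rigidly offset MRI
    volumes), detection of RF-corrupted sinogram frames with intensity maps and
    corruption power spectra, robust sinogram restoration to 1 Hz, filtered
    back-projection reconstruction with a two-region speed of sound model and
    interface segmentation, linear spectral unmixing into oxy- and
    deoxy-hemoglobin with exponential fluence correction, rigid multimodal
    coregistration and reslicing, and oxygen-challenge functional time-course
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    minpack.lm,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
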