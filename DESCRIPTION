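Package: fustherm
Title: PRF-Shift and Referenceless MR Thermometry for Focused-Ultrasound
    Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Temperature monitoring tools for magnetic resonance guided
    focused ultrasound (MRgFUS): classical proton resonance frequency (PRF)
    shift temperature mapping from gradient-echo phase images, referenceless
    thermometry by radial basis function and weighted polynomial
    extrapolation of the background phase surrounding a heated region,
    Rician-corrected signal-to-noise estimation for magnitude images, a
    synthetic phantom and sonication simulator with stored ground truth, and
    a study pipeline comparing reconstruction methods with paired Wilcoxon
    signed-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
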