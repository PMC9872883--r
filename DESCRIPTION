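Package: muellertomo
Title: 3D Mueller-Matrix Image Reconstruction of Tissue Optical Anisotropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential (logarithmic) decomposition of per-pixel 4x4 Mueller
    matrices into maps of linear and circular birefringence and dichroism at
    selectable phase planes, an off-axis polarization-holography forward
    simulator with Fourier-sideband demodulation, first- to fourth-order
    statistical-moment characterization of the anisotropy maps, and a
    single-threshold diagnostic classifier for two-group (benign/malignant)
    tissue discrimination.  A synthetic tissue-phantom generator with frozen
    adenoma/carcinoma presets makes the whole chain verifiable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
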