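Package: qustex
Title: Quantitative Ultrasound Texture-Derivative Radiomics
Version: 0.1.0
Authors@R:
    person("QUS", "Radiomics Contributors", email = "qustex@example.org",
           role = c("aut", "cre"))
Description: Spectral quantitative-ultrasound (QUS) parameter estimation from
    raw radiofrequency (RF) echo data using the reference-phantom method
    (mid-band fit, spectral slope, 0-MHz intercept, average scatterer
    diameter, average acoustic concentration), grey-level co-occurrence
    matrix (GLCM) texture analysis of the resulting parametric maps, and
    second-pass "texture derivative" (texture-of-texture) features.
    Includes a point-scatterer pulse-echo RF simulator that provides ground
    truth for every stage, and a treatment-response classification protocol
    (balanced subsampling, sequential forward feature selection, linear
    discriminant / k-nearest-neighbour / RBF support-vector classifiers,
    leave-one-out cross-validation) with a full evaluation panel.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
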