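Package: phlimr
Title: Quantitative Sub-Cellular pH Mapping from Phasor FLIM Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for pH-dependent fluorescence lifetime imaging (pHLIM)
    with the mApple biosensor: per-pixel phasor analysis of photon-arrival
    decay cubes, linear G-to-pH calibration with 95 percent prediction bands,
    four-parameter logistic intensity calibration with inverse-prediction
    uncertainty, automated vesicle detection with label-mask post-filtering,
    per-vesicle intensity-weighted pH quantification and time-course
    comparison, plus a synthetic FLIM generator encoding mApple photophysics
    so the whole pipeline is exercisable without a microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
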