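Package: crcsf
Title: Simulated Measurement of the Contrast Sensitivity Function from the
    Campbell-Robson Chart and a QUEST Gold Standard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether the visibility boundary on a
    Campbell-Robson chart traces the observer's contrast sensitivity function
    (CSF). Implements the truncated log-parabola CSF model and its three-click
    chart parameterisation, log-swept chart and Gabor-grating rendering with
    noisy-bit dithering, a QUEST Bayesian adaptive staircase with the
    seven-frequency session protocol, a calibrated synthetic-observer
    generator, the group-level descriptive and paired statistics, and a nested
    cross-validated support-vector regression analysis with a permutation
    null. An end-to-end driver replays the whole study on synthetic
    populations of adults and children.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
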