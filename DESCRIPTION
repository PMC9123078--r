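Package: polspike
Title: Spike-Train Analysis of Polarization-Angle Tuning in Insect
    Central-Complex Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how polarization-sensitive neurons encode
    the angle of polarization (AoP) of light at different degrees of
    polarization (DoP). Implements axial circular statistics (angle
    doubling, mean resultant vector length), circular-linear correlation
    tests of AoP tuning, bimodal von Mises tuning-curve fits, background
    activity statistics, DoP-dependence regressions with Lilliefors-based
    model selection, and estimation of the DoP threshold for reliable AoP
    coding from no-stimulus controls. Includes an inhomogeneous-Poisson
    spike-train simulator with cell-type presets emulating intracellular
    recordings under a rotating-polarizer protocol, so the full pipeline
    is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
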