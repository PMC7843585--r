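Package: maizecanopy
Title: Maize Canopy Morphology Under Increased Plant Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts final maize organ morphology (lamina, sheath and
    internode dimensions) per phytomer as a function of plant density using
    log-linear response equations fitted by phytomer group, reconstructs the
    corresponding three-dimensional plant and canopy geometry, validates
    simulations against measurement tables with a normalized RMSE statistic
    and quality bands, and renders percent-change heatmaps of organ size
    across successive density increases. Includes a synthetic field-trial
    data generator so the full pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    rlang,
    ggplot2,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
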