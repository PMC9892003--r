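Package: polysomix
Title: Reciprocal Neighbourhood Analysis of Ribosome Fields from Cryo-Electron Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spatial organisation of ribosomes in
    cryo-electron tomograms after subtomogram averaging. Reads particle
    metadata (positions, Euler orientations, state and translocon-population
    labels) from STAR tables, builds per-population 3D neighbour-probability
    histograms in the particle reference frame, derives trailing/leading
    direction masks, confirms polysome links by the reciprocal mask criterion
    and assembles chains, and fits a multinomial mixed-effects logistic
    regression (tomogram as random intercept) relating ribosome state to
    polysome association, with Wald tests, Hochberg adjustment, confidence
    intervals and fold increases over random association. A synthetic
    vesicle-scene generator with planted polysome geometry makes every stage
    testable without tomographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    ggplot2,
    optparse
Config/testthat/edition: 3
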