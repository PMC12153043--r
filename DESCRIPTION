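Package: diatomech
Title: Mechanics of Diatom Proliferation in Agar Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the mechanics of unicellular algae
    (diatoms) dividing while entrapped in agar hydrogels. Fits spherical
    (Hertzian) indentation and stress-relaxation curves to extract
    instantaneous and residual elastic moduli, relaxation timescales and
    their power-law scaling with agar concentration; detects and links
    fluorescent tracer beads in image stacks (particle tracking
    velocimetry) and maps displacement and infinitesimal-strain fields
    around an expanding cell; implements a cavitation-criterion growth
    model (division proceeds when turgor pressure exceeds the gel's
    residual modulus) with two-regime concentration laws for division
    time, expansion and viability; and computes colony cultivation
    statistics with a stochastic colony growth simulator. All pipeline
    inputs can be generated synthetically with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
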