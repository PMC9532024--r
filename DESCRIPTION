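Package: collatflow
Title: Steady-State Cerebral Blood Flow with Collaterals and Permeable Thrombi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates steady-state one-dimensional cerebral blood flow on
    synthetic vascular networks with tunable leptomeningeal collateral
    density. Vessels are compliant tubes coupled through Kirchhoff mass
    balance; outlet resistances are calibrated to inlet boundary conditions
    and iterated under a cerebral autoregulation model. A permeable thrombus
    is represented as a Darcy porous element, enabling permeability and
    length sweeps, infarct-volume estimation by fractional flow-change
    thresholding, and inversion of dynamic-CTA-style thrombus measurements
    (transit time, void fraction, length, lumen area) into effective
    permeability, pressure drop and infarct estimates per collateral grade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
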