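Package: nanosampler
Title: Simulation and Analysis Toolkit for a Syringe-Based Nanoliter
    Autosampler
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free control and analysis stack for a modified low-cost
    pipetting robot used as a nanoliter liquid handler and nano-LC autosampler.
    Provides three-corner affine plate calibration with persistent calibration
    files, syringe plunger kinematics with a piecewise volume conversion table,
    deterministic simulated devices (motion controller, selector and
    two-position valves, GPIO signal bridge, temperature deck) driven by a
    virtual clock, a valve-connectivity fluid network with one-dimensional
    sample-plug tracking and loop underfill/overfill injection planning, a
    YAML method-file interpreter with LC-pump handshaking and gradient-profile
    utilities, and analysis of fluorescein dilution assays used to verify
    sub-microliter dispensing, including a synthetic assay generator.
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
    purrr,
    R6,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
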