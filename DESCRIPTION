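Package: tonbpull
Title: Single-Molecule Force Spectroscopy of TonB-Dependent Transporter Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for atomic-force-microscope (AFM) single-molecule
    force spectroscopy of the TonB / TonB-dependent-transporter interaction:
    worm-like-chain (WLC) polymer elasticity and contour-length bookkeeping,
    force-curve preprocessing (baseline and contact-point zeroing), rupture-event
    detection and fixed-persistence WLC fitting with acceptance filters,
    contour-length-increment (delta-Lc) statistics with single-Gaussian modal
    fits, dynamic force spectra with Bell-Evans parameter extraction, and
    microscale-thermophoresis (MST) dissociation-constant fitting by the exact
    1:1 law of mass action. Includes seeded Monte-Carlo generators for
    constant-velocity pulling experiments (Bell-kinetics rupture through a
    serial mechanical network, non-specific adhesion and empty traces) and MST
    titrations, used as ground truth throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
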