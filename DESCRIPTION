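Package: tirfkin
Title: Two-Color Single-Molecule TIRF Colocalization, Step Counting, and
    Binding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of interleaved two-camera single-molecule TIRF
    recordings of ligand binding to surface-immobilized multimeric
    proteins: channel registration and deinterleaving, spectral leakage
    and autofluorescence correction, diffraction-limited spot detection
    and trace extraction, shifted cross-correlation colocalization, a
    four-pass step finder for photobleaching and binding steps,
    stoichiometry by step counting, signed residence-time kinetics with
    photobleaching correction, and Poisson occupancy models. Includes a
    virtual-movie simulator with realistic EMCCD noise for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    graphics,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
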