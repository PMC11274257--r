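Package: eisdep
Title: Equivalent-Circuit Analysis of Impedance Spectra and
    Dielectrophoresis Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain from electrochemical impedance spectroscopy (EIS)
    to a dielectrophoresis (DEP) response prediction for suspended particles.
    Fits Randles equivalent-circuit parameters (solution resistance,
    constant-phase element, Warburg diffusion element, polarization
    resistance) to impedance spectra by weighted complex nonlinear least
    squares, derives suspension conductivity from parallel-plate cell
    geometry, converts impedance to complex permittivity, and predicts the
    sign and crossover frequencies of the DEP force via the
    Clausius-Mossotti factor and the Maxwell-Wagner dielectric mixture
    model. Includes a seeded synthetic-spectrum generator emulating a
    nanomolar Tau-441 protein dilution series.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
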