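Package: fracwk
Title: Fractional-Order Windkessel Modelling of Aortic Input Impedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frequency-domain analysis of aortic pressure-flow
    relationships with lumped-parameter Windkessel models. Implements the
    fractional-order two-element Windkessel (FWK2), in which the arterial
    compliance is a fractional-order capacitor (constant-phase element),
    alongside the classical two-element (WK2), three-element (WK3) and
    viscoelastic (VWK) Windkessel models. Provides Fourier harmonic
    decomposition of periodic waveforms, empirical aortic input impedance
    spectra, gain-normalized transfer-function calibration with a full
    goodness-of-fit metric suite, dynamic (complex, frequency-dependent)
    compliance formulas, and a synthetic virtual-cohort generator for
    offline validation and benchmarking.
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
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
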