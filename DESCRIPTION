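Package: vdwcomb
Title: Van der Waals Pair Potentials, Combination Rules, and Second Virial Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workbench for developing and evaluating van der Waals pair
    potentials for noble-gas-like systems. Fits nine analytic potential
    families (Lennard-Jones 12-6/8-6/buffered 14-7, Morse, four Buckingham
    variants, Tang-Toennies) to dimer dissociation curves inside a
    configurable energy window, exhaustively permutes combination relations
    (Lorentz-Berthelot, Waldman-Hagler, Hogervorst, Halgren and power-mean
    rules) to reconstruct heterodimer parameters from homodimer fits and
    ranks rule sets by windowed RMSE, computes semiclassical second virial
    coefficients with quantum corrections to third order, and evaluates the
    Axilrod-Teller triple-dipole three-body dispersion energy. Includes a
    seeded synthetic dissociation-curve generator so every operation is
    testable without external data, plus complete-basis-set extrapolation
    and enthalpy-of-vaporization helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
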