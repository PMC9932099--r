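Package: cdbind
Title: Host-Guest Binding Analysis for NMR Titration Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determination of host-guest association constants from fast-exchange
    NMR chemical-shift titration data, aimed at cyclodextrin inclusion complexes.
    Provides equilibrium speciation solvers for arbitrary HmGn binding models,
    global nonlinear least-squares fitting of binding constants shared across
    reporter protons, a two-state ("self-competitive") extension with
    identifiability diagnostics, continuous-variation (Job plot) simulation and
    stoichiometry diagnostics, titration experimental-design calculators, ln K
    to free-energy conversion, affinity versus simulation-energy comparison,
    and a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
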