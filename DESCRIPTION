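Package: vacdry
Title: Vacuum Drying Kinetics, Diffusivity, Thermodynamics and Economics of Thin-Layer Herb Drying
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for thin-layer vacuum drying experiments on leafy
    herbs (developed around sage, Salvia officinalis). Converts raw load-cell
    weight series into moisture ratios, fits a nine-model thin-layer bank
    (Page, Midilli, Weibull family and relatives) by nonlinear least squares
    with n-p goodness-of-fit statistics, derives effective moisture diffusivity
    from the Fickian slab solution, estimates Arrhenius activation energy and
    Eyring transition-state thermodynamics (activation enthalpy, entropy and
    Gibbs free energy), and closes with a batch-dryer techno-economic model
    (annualized costs, throughput, savings cascade, inflation-adjusted payback).
    Includes a synthetic drying-curve generator emulating the experimental
    design so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
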