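Package: mycosorb
Title: Dose-Response and Biosorption Kinetics of Heavy Metals on Fungal Biomass
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of fungal metallotolerance and heavy-metal
    biosorption. Estimates IC50 and Hill slope from plate tolerance indices by
    multistart nonlinear least squares with bootstrap confidence intervals;
    computes specific uptake, removal efficiency, and Langmuir/Freundlich
    isotherm quantities from batch sorption experiments; fits the
    isotherm-coupled kinetic differential equation for liquid-phase metal
    depletion (first- or second-order kinetics crossed with Langmuir or
    Freundlich equilibrium) by numerical integration and seeded multistart
    least squares, with model selection across the four combinations; and
    generates synthetic plate and time-course datasets for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
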