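Package: comres
Title: Ecological Costs and Benefits of Antibiotic Resistance in Commensals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a two-species (pathogen-commensal)
    Lotka-Volterra model of antibiotic treatment. Provides closed-form
    equilibria with local stability classification, gradient conditions for
    competitive release and beneficial commensal resistance, two-dimensional
    parameter sweeps over antibiotic exposure and relative commensal
    susceptibility, temporal dynamics via ODE integration, resource-explicit
    (chemostat) and spatial reaction-diffusion robustness variants, and a
    within-host infection-risk optimisation that balances the benefits of
    commensal resistance against horizontal gene transfer and opportunistic
    infection costs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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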