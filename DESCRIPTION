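Package: airwaymorph
Title: Mechanochemical Morphoelastic Simulation of Asthmatic Airway Remodelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates long-term remodelling of an asthmatic airway as a
    two-layer morphoelastic cylinder. Airway smooth muscle and extracellular
    matrix volume fractions evolve under repeated inflammatory or contractile
    agonist challenges, with quasi-static nonlinear elastic equilibrium
    (fibre-reinforced hyperelastic wall, Hill-type active contraction) solved
    at every growth step and fibre-direction stress feeding back on phenotype
    switching, proliferation and agonist release. Includes passive material
    parameter fitting from pressure-radius data, synthetic data generation,
    challenge-protocol orchestration and two-parameter sweep experiments, with
    tidy tabular outputs and ggplot2 visualisation.
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
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
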