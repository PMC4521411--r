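Package: alveosim
Title: Stochastic Simulation of Nanoparticle Fate in the Alveolar Lining Fluid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constant-number direct-simulation Monte Carlo modelling of
    engineered nanoparticle transformation and transport in the pulmonary
    alveolar lining layer. Simulates Brownian agglomeration with DLVO and
    steric interactions, oxidative dissolution, surfactant lipid-vesicle
    adsorption and rupture into bilayer patches, coverage-dependent
    surfactant-protein (SP-A/B/C/D) corona formation, and vertical transport
    by gravitational settling (in vitro) or surface-tension-driven immersion
    (in vivo). Includes calibration scenarios for published in vitro studies,
    extraction of kinetic rates (agglomeration, transport, dissolution,
    phospholipid and protein adsorption), replicate averaging, and local
    one-at-a-time sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
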