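Package: braintherm
Title: Lumped-Parameter Bioheat Modelling of Regional Hyperthermia in
    Brain Tumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates temperature and blood-perfusion dynamics of a brain
    tumour, its surrounding healthy tissue and the systemic blood during
    regional hyperthermia, using a three-compartment energy-balance model
    with temperature-dependent perfusion, sweat and skin-convection heat
    loss, and stochastic tumour blood-flow forcing.  Includes a
    Hagen-Poiseuille bifurcating vascular-network model that derives the
    tumour flow-impairment parameter as a ratio of total network
    resistances, local finite-difference sensitivity analysis, treatment
    scenario engines (single runs, ensembles, parameter maps, basal
    perfusion sweeps) and a command-line interface for reproducible
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
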