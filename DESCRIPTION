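Package: arisaemasim
Title: Population Dynamics of Lethal Deceptive Pollination Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for the coupled population dynamics of trap-flower
    plants (Arisaema-type sequential hermaphrodites) and the male fungus
    gnats they attract and kill. Implements the per-visit choice
    probabilities and lifetime visit statistics (expected pollen-carrying
    visits Q1, copulations Q2, and trap probability P) of a male insect,
    a stage- and sex-structured plant model coupled to an insect model
    through Holling type-II pollination and mating success, the analytic
    plant-persistence condition, steady-state classification under an
    extinction threshold, and parameter-space regime mapping for
    disturbance scenarios. A Monte Carlo visit-sequence simulator serves
    as an independent check on the combinatorial expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
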