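Package: avmemb
Title: Multi-Stage Cerebral AVM Embolization by Two-Phase Filtration,
    a Monotone CABARET Scheme and Particle-Swarm Optimal Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates endovascular embolization of a cerebral arteriovenous
    malformation (AVM) as one-dimensional two-phase filtration of blood and
    embolic agent with redistribution of blood into the surrounding healthy
    vessels. The nonconvex scalar conservation law with an integral inlet
    boundary condition is solved by a monotone modification of the CABARET
    finite-difference scheme; multi-stage interventions are chained through
    cross-section reduction by the solidified agent. Optimal per-stage
    injection schedules (trapezoid intensity profiles) are found by a modified
    particle swarm method with penalty terms for the clinical safety
    constraints (no agent breakthrough into the vein, bounded inlet pressure).
    Includes synthetic patient generators, an analytic Buckley-Leverett
    (Welge) reference solution, YAML configuration round-trips and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
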