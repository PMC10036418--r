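Package: bbbpk
Title: Physiologically Based Pharmacokinetic Modelling of Brain Delivery
    of Plasma-Protein-Bound Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates brain delivery of drugs bound to plasma proteins
    (albumin and alpha-1-acid glycoprotein) with a partly flow, partly
    compartmental model of the brain capillary and post-vascular brain.
    Provides the closed-form steady-state solution for all capillary and
    brain variables, an independent stationary-point oracle, stiff ODE
    time courses after a single oral dose with trapezoid AUC summaries,
    and a declarative scenario engine for parameter-perturbation studies
    of plasma-protein-mediated uptake (PMU), active efflux, brain
    metabolism, and brain tissue binding. Includes built-in parameter
    sets for propranolol and imipramine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
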