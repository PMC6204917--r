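Package: navblock
Title: State-Dependent Block Analysis for Voltage-Gated Sodium Channel
    Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for voltage-clamp pharmacology of
    voltage-gated sodium (and potassium) channel block. Implements
    Hill-Langmuir concentration-response fitting, Boltzmann gating-curve
    analysis (activation and steady-state fast inactivation), mono- and
    biexponential block-onset and recovery-from-inactivation kinetics, a
    resting/inactivated two-receptor-state model of voltage-dependent
    apparent potency, automated patch-clamp plate quality control and
    vehicle-corrected normalization, and a modified Hodgkin-Huxley
    simulation of cortical-neuron excitability under channel block.
    Includes a seeded synthetic-data generator emulating
    concentration-response plates, gating families, recovery series,
    block-onset time courses and pulse-train state-dependence protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
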