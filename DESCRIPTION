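Package: ventstrain
Title: Multi-Compartment Lung Mechanics, Intracycle Power and Strain
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates passive mechanical ventilation of a heterogeneous
    five-compartment lung modelled as a resistive airway tree feeding linear
    elastic compartments. Solves the Kirchhoff pressure/flow balances of the
    network as a linear ODE system, finds the periodic (cycled) steady state
    including per-compartment auto-PEEP, and derives the energetics of each
    compartment: intracycle elastic power, cumulative elastic energy, strain,
    strain rate and maximal strain. Supports constant-flow, decelerating-flow,
    sinusoidal-flow and constant-pressure inspiratory drives, amplitude
    calibration to a target tidal volume, and scripted in-silico experiments
    (PEEP sweeps, tidal-volume by peak-flow grids, resting-volume sweeps,
    heterogeneous resting volumes) with tidy CSV/JSON export and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
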