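Package: rad51kin
Title: Simulation and Quantification of Recombinase Filament Assembly from
    Single-Molecule Experiments
Version: 0.1.0
Authors@R:
    person("Ondrej", "Vana", email = "ondrej.vana@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying RAD-51 nucleoprotein filament assembly on
    single-stranded DNA from dual-trap optical-tweezers fluorescence
    experiments, together with a kinetic Monte Carlo simulator that provides
    ground truth for every analysis stage. Includes exact-stochastic
    (Gillespie) simulation of filament nucleation, growth, burst dissociation
    and mediator 5'-end capping on a one-dimensional lattice; rendering of
    event logs into multi-channel kymographs, force traces and photobleaching
    traces; worm-like chain and freely-jointed chain force-extension fitting
    with ssDNA gap-length estimation; RPA-displacement and nucleation-counting
    kymograph analysis; maximum-likelihood photobleaching step counting with
    double-Gaussian unit calibration; dwell-time survival analysis and
    power-law nucleation kinetics; and filament-end localization of mediator
    binding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
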