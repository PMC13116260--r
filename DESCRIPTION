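Package: cavthz
Title: Langevin Dynamics and Coherence of Calcium Ions in a Channel
    Selectivity Filter under Terahertz Driving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the axial dynamics of calcium ions confined in the
    selectivity filter of the bacterial voltage-gated calcium channel CavAb.
    Provides a parameterized electrostatic channel model (EEEE-locus ring
    charges, mouth dipoles, dielectric self-energy, confining walls,
    transmembrane voltage), a BAOAB Langevin integrator with optional
    terahertz field driving and a reset boundary for permeation counting,
    frequency-domain analysis (acceleration and distance spectra,
    magnitude-squared coherence, radiative coherence enhancement factor),
    potential-of-mean-force construction by Boltzmann inversion, a sparse
    finite-difference solver for the two-ion time-independent Schroedinger
    equation with coupled-quantum-harmonic-oscillator mode fingerprinting,
    and exact Poisson rate inference for rare permeation events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    methods,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
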