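Package: ionphase
Title: Salt- and Ion-Valency-Modulated Phase Separation of Charged Disordered Proteins
Version: 0.1.0
Authors@R:
    person("ionphase", "developers", email = "ionphase@example.org", role = c("aut", "cre"))
Description: Sequence-specific tools for studying liquid-liquid phase separation
    (LLPS) of charged intrinsically disordered protein regions in the presence of
    counterions, salt, and ATP-magnesium. Provides an analytical phase-equilibrium
    engine based on a renormalized-Gaussian random phase approximation augmented
    with Flory-Huggins interactions (rG-RPA+FH), coexistence and tieline solvers
    for fixed-salt binodals and two-dimensional salt-polymer phase diagrams with
    Donnan-consistent ion partitioning, a fitting routine for effective
    permittivity and Flory-Huggins energy parameters against coexistence data, a
    lattice field-theoretic simulator using complex-Langevin dynamics with
    multi-bead ion species, a coarse-grained explicit-ion molecular dynamics
    energy model with slab-profile analysis, and a counterion-bridging trajectory
    analyzer. Deterministic synthetic-data generators make every analysis stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
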