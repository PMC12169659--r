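Package: sqdpcm
Title: Sample-Based Quantum Diagonalization with IEF-PCM Implicit Solvent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantum-centric ground-state electronic-structure workflow for
    small closed-shell solutes in a dielectric continuum. Electron
    configurations are sampled from a simulated local unitary cluster Jastrow
    (LUCJ) state, noise-broken particle-number and spin-z symmetries are
    repaired by self-consistent configuration recovery (S-CORE), and the
    molecular Hamiltonian is diagonalized in the sampled determinant subspace
    under an integral-equation-formalism polarizable continuum model (IEF-PCM)
    reaction field, yielding total free energies and solvation free energies.
    Includes a self-contained Gaussian-integral/RHF/CCSD engine, a
    boundary-element IEF-PCM solver, a string-based determinant CI with
    Davidson diagonalization, and a full-sector CASCI IEF-PCM reference mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
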