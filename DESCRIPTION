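Package: hyperpol
Title: Electronic and Vibrational First-Order Hyperpolarizability Analysis
Version: 0.1.0
Authors@R: person("hyperpol", "developers", role = c("aut", "cre"),
    email = "hyperpol@example.org")
Description: Tools for analysing molecular first-order hyperpolarizabilities
    (beta) in gas phase and solution: finite-field extraction of dipole,
    polarizability and hyperpolarizability tensors from dipole-versus-field
    samples with Richardson/Romberg refinement; rotational invariants
    (beta_vec) under Kleinman or jk index symmetry; double-harmonic pure
    vibrational beta from normal-mode dipole and polarizability derivatives
    with infinite-frequency EOPE/SHG limits; hyperpolarizability-density
    analysis on Gaussian cube grids; Lorentzian IR/Raman spectral
    simulation; frequency-dispersion and solvent-ratio bookkeeping; and a
    synthetic model-molecule generator with analytically known responses
    used as the test oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
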