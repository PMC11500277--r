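Package: deltapes
Title: Delta-Machine-Learning Potential Energy Surfaces with
    Permutationally Invariant Polynomials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits molecular potential energy surfaces (PES) as linear
    expansions in permutationally invariant polynomials (PIPs) of Morse
    variables, and elevates a cheap low-level surface (a fitted PES or a
    classical bond/angle/dihedral force field) toward coupled-cluster
    quality by adding a small, separately fitted correction surface
    (delta-machine-learning).  Includes symmetrized-monomial basis
    construction with a Burnside cross-check, weighted linear
    least-squares fitting of energies and analytic Cartesian gradients,
    energy-window filtering, a classical intramolecular force field with
    harmonic or Morse bond stretches, geometry optimization,
    finite-difference Hessians, harmonic normal-mode frequencies, rigid
    torsional scans, gradient-fidelity metrics, and a synthetic surrogate
    data generator so the full pipeline is testable without external
    electronic-structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
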