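Package: redoxpb
Title: Continuum Electrostatics of Protonation and Redox Equilibria in
    Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finite-difference linearized Poisson-Boltzmann calculations of
    site pKa values and redox midpoint potentials (Em) in proteins, with
    three-step grid focusing, Metropolis Monte Carlo equilibration of all
    titratable sites against an exact-enumeration backend, decomposition of
    Em shifts into solvation-loss and protein-charge terms, transmembrane
    electric-field mapping with Gaussian-smeared charges, and hole-hopping
    kinetics along residue chains via the Moser-Dutton ruler. Includes
    synthetic fixture generators (Born ions, Kirkwood spheres, layered
    membrane-protein mimics, interacting titratable-site clusters, coupled
    redox-proton pairs) so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
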