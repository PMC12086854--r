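Package: vcdpt
Title: Vibrational Circular Dichroism and Infrared Spectra from
    Atomic-Orbital Linear Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: All-electron restricted Hartree-Fock mean field with analytic
    Gaussian integrals and a density-matrix linear-response solver working
    entirely in the atomic-orbital basis, validated against an independent
    molecular-orbital Sternheimer solver.  Implements nuclear displacement,
    nuclear velocity (velocity-gauge atomic orbitals) and magnetic field
    (gauge-including atomic orbitals) perturbation theories, assembles
    atomic polar and axial tensors, rotational and dipole strengths, and
    synthesizes Lorentzian-broadened vibrational circular dichroism and
    infrared spectra for small closed-shell molecules.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
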