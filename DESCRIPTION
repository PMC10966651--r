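Package: mwmd
Title: Nonequilibrium Molecular Dynamics with Separate Rotational and
    Translational Solvent Thermostats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale molecular dynamics engine and analysis suite for
    studying microwave-like heating of aqueous solutions via a replacement
    model: instead of an explicit oscillating electric field, the rotational
    kinetic temperature of rigid three-site water is thermostatted above its
    translational temperature using three independent weak-coupling
    (Berendsen) heat baths (solute, solvent translation, solvent rotation).
    Includes rigid-water constraint dynamics (SETTLE and SHAKE), leapfrog
    integration, reaction-field electrostatics with group-based cutoffs,
    steepest-descent minimization, system builders (water boxes, solvation,
    ion placement, toy peptides), a staged equilibration protocol, and
    trajectory analyses (RMSD, RMSD100, RMSF, radius of gyration,
    head-to-tail distance, hydrogen bonds, solvent-accessible surface area
    with a polar/nonpolar split, energy decomposition, block-averaged
    uncertainties, and paired condition comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    bio3d
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
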