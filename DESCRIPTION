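Package: sptcrowd
Title: Scaled Particle Theory Analysis of Protein Association in Crowded
    Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic statistical mechanics of protein (gamma-crystallin)
    association equilibria in macromolecular crowded media.  Implements
    scaled particle theory (SPT) activity coefficients for hard convex
    solutes (spheres and spherocylinders), two models of intermolecular
    attraction -- a thermodynamic perturbation model (TPM) with an
    orientationally averaged square-well depth, and a chemical binding
    model (CBM) with discrete surface binding sites -- the crowding factor
    of the dimerization equilibrium, osmotic pressure isotherms from the
    density-dependent activity coefficient, least-squares fitting of the
    attraction parameters to osmotic-pressure data, entropy-enthalpy
    compensation (crossover) solvers, and a seeded synthetic-isotherm
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
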