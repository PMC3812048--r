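Package: stringpmf
Title: String-Method and Umbrella-Sampling Free-Energy Workflows for
    Transporter Gating
Version: 0.1.0
Authors@R:
    person("stringpmf", "maintainers", email = "maintainers@stringpmf.dev",
           role = c("aut", "cre"))
Description: Tools for dissecting ion-dependent gating of LeuT-fold secondary
    transporters in a low-dimensional collective-variable space: gate-distance
    and ion-displacement order parameters computed from PDB coordinates, analytic
    multi-basin model landscapes with an overdamped Langevin engine, path
    initialization by RMSD steering, minimum free energy path refinement with the
    string method with swarms of trajectories, umbrella sampling with harmonic
    restraints, 2D potential-of-mean-force reconstruction by WHAM with
    block-based uncertainties and strip-integrated 1D profiles, and basin,
    barrier and state free-energy analysis of the resulting landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
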