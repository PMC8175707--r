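Package: ftszmech
Title: Quantification of FtsZ-Induced Membrane Deformation Mechanics
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image and signal analysis for in vitro reconstitution assays of
    FtsZ-driven membrane deformation. Provides circular-ROI kymographs and
    treadmilling-velocity estimation, helical lipid-tube geometry
    quantification (diameter, arclength, protein density, helical pitch),
    single-ring brightness and diameter measurement, optical-tweezers
    calibration (position response, power-spectrum trap stiffness) and
    oscillation-mode spring-constant estimation, elastic-rod mechanics
    linking spring constants to flexural rigidity and Young's moduli, and
    distribution statistics (bimodal pitch states, morphology proportions).
    A synthetic-data module generates all inputs (helical tube stacks,
    vortex movies, driven-bead detector traces, ring fields) with stored
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
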