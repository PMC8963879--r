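Package: colonyorder
Title: Radial Orientational Order in Inward-Growing Bacterial Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the emergence of large-scale
    radial (aster, +1 defect) orientational order when rod-shaped bacteria
    grow inward into a closed void. Provides an overdamped two-dimensional
    hard-rod (spherocylinder) simulator of growing, dividing colonies with
    Hertzian contact repulsion and substrate drag; a finite-difference solver
    for the growing active-nematic continuum model (density, Q-tensor and
    damped momentum equations with a Landau-de Gennes molecular field);
    closed-form radial velocity and growth-rate profiles with the
    flow-alignment orientation ODE and its stability analysis; measurement
    operators (radial order parameter, coarse-grained Q and scalar order,
    per-cell virial stress with polar transform, tracked radial velocity
    profiles, critical-radius estimation, packing fraction, structure-tensor
    director fields from images); strain-competition protocols for
    division-length races during inward growth; and synthetic-data generators
    for all measurement stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
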