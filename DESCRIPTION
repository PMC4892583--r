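Package: armflex
Title: Bend and Twist Dynamics of Alpha-Solenoid Repeat Proteins
Version: 0.1.0
Authors@R:
    person("armflex", "developers", email = "armflex@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the collective motions of alpha-solenoid
    repeat proteins (armadillo-repeat importins and relatives) and their
    peptide complexes. Provides multi-model PDB input/output and Kabsch
    superposition; reference-structure (Lyman-Zuckerman) clustering of
    merged trajectories with per-replicate convergence tables; Calpha
    anisotropic elastic-network normal modes with degree-of-collectivity,
    mode-displacement conformer grids and restraint-energy screening;
    principal component analysis of Calpha displacement covariance and
    normal-mode/principal-component overlap; dynamic cross-correlation
    maps; solenoid bend/twist geometry (three-anchor radius of curvature
    and inter-repeat helix-axis angles); and per-contact occupancy of salt
    bridges, hydrogen bonds and hydrophobic contacts at a protein-peptide
    interface. Includes a synthetic solenoid-trajectory generator with
    analytically known bend/twist amplitudes and contact schedules for
    ground-truth validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
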