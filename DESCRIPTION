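Package: simtraj
Title: Molecular Dynamics Trajectory Analysis for Membranes, Proteins and
    Non-Bonded Interactions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A project-configured toolkit for analysing molecular dynamics
    trajectories stored as PDB structures with DCD (or multi-model PDB)
    coordinate files.  Provides membrane observables (area per lipid by
    periodic Voronoi tessellation, deuterium order parameters, bilayer
    thickness, sterol tilt, area compressibility modulus, density profiles,
    lateral diffusion), protein observables (Kabsch-superposed RMSD and RMSF,
    DSSP secondary structure, pore radius profiles, covariance analysis),
    contact and radial-distribution analyses, geometric detectors for
    hydrogen bonds, salt bridges, pi stacking and water bridges, box-size and
    solution-diffusion utilities, a registry-driven command-line dispatcher
    with reproducibility logging, and seeded synthetic-fixture generators
    with analytically known ground truth for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
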