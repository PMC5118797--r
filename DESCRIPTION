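Package: immopsn
Title: Adsorption, Correlation-Network and Binding-Energy Analysis of
    Enzyme-Nanotube Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-simulation analysis stack for enzymes immobilized on
    carbon nanotubes: armchair nanotube coordinate generation,
    solvent-accessible surface area and buried contact area, adsorbed-atom
    counts and solvent spatial-density grids, RMSD/RMSF and binding-pocket
    strand distances, Calpha dynamical cross-correlation matrices,
    protein-structure-network communication paths with correlation
    filtering and dominant-path statistics, and a single-trajectory
    MM-GB(SA)-style binding free energy with per-residue decomposition.
    Includes seeded synthetic-trajectory generators with known ground
    truth so every stage is testable without simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    MASS,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
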