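Package: oligotraj
Title: Trajectory Analysis of Peptide Oligomerization with Lipids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for molecular-dynamics trajectories of
    amyloid-beta (1-42) peptides co-aggregating with POPC lipids:
    aggregation-state detection from minimum-distance contact graphs,
    mass-weighted radius of gyration and inertia-tensor eccentricity,
    GROMOS (Daura) conformational clustering on backbone RMSD, weighted
    residue-residue and residue-lipid-region interaction frequency maps,
    geometric hydrogen-bond detection, Shrake-Rupley solvent-accessible
    surface area with hydrophobic partitioning, simplified secondary
    structure summaries, per-residue energy (ddG) comparisons from FoldX
    SequenceDetail tables, and an assumption-driven statistical comparison
    framework with FDR control. Includes synthetic-trajectory generators
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    bio3d,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
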