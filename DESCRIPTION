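Package: dockboxr
Title: Ligand-Size-Adaptive Docking Box Construction and Virtual Screening Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs molecular docking search spaces sized to the ligand at
    hand: an optimized cubic box whose edge is 2.857 times the ligand radius of
    gyration (equivalently, a radius-of-gyration-to-edge ratio of 0.35),
    alongside an emulation of the AutoDock Vina default box protocol (bounding
    box + 10 Angstrom, a random extra 5 Angstrom per dimension, 22.5 Angstrom
    floor) and a box-edge sweep protocol. Also provides docking-pose evaluation
    (heavy-atom RMSD without superposition, distance-cutoff protein-ligand
    contact recovery at atom and residue granularity), virtual-screening
    ranking metrics (enrichment factors, BEDROC, rank-based enrichment AUC,
    ACT-50%), nonparametric comparison tests (Mann-Whitney U, Wilcoxon
    signed-rank, with exact enumeration at small sample sizes), readers and
    writers for SD, PDB and PDBQT-coordinate ligand/protein structures and
    Vina-style configuration files, plus a synthetic benchmark harness with a
    mock docking backend that reproduces the box-size sweep experiment at desk
    scale.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
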