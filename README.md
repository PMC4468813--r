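# dockboxr

Sizing the search space for molecular docking — and knowing whether it
helped.

## The problem

Docking engines such as AutoDock Vina explore an axis-aligned box around a
binding pocket. Pick the box too small and the correct binding mode cannot
even fit inside it (sampling failure); pick it too generously and the
engine ranks spurious placements above the native one (scoring failure).
The stock recipe needs the co-crystallized ligand: take its bounding box,
add 10 Å per dimension, extend a randomly chosen side of each dimension by
a further 5 Å, and enforce a 22.5 Å minimum edge. That requires coordinates
of a bound ligand — which are unavailable for exactly the targets where
docking is most needed — and one fixed box cannot suit compounds of very
different sizes.

`dockboxr` implements a ligand-size-adaptive alternative: a cubic box whose
edge is proportional to the query compound's radius of gyration,

```
Rg = sqrt( (1/N) * sum_k | r_k - r_center |^2 )        (heavy atoms only)

edge = Rg / 0.35  =  2.857 x Rg
```

centered on the pocket (experimental or predicted). The Rg-to-edge ratio of
0.35 is the accuracy optimum found by sweeping cubic box edges from 2 to
36 Å in 2 Å steps over a large protein–ligand benchmark; the package ships
the sweep machinery, the evaluation metrics and a synthetic mock-docking
harness so the experimental design itself is reproducible at desk scale.

## What's in the box

* **Structure I/O** — SD (V2000) read/write, PDB via `bio3d`,
  PDBQT coordinate extraction, Vina-style config files; benchmark curation
  filters (6–100 heavy atoms, non-covalent; 50–600 residues).
* **Geometry** — `radius_of_gyration()`, rotamer-ensemble Rg summaries,
  Haar-uniform `random_reorientation()`, pocket recentering, the 8 Å
  pocket-prediction success criterion.
* **Boxes** — `optimized_box()`, `default_box()` (Vina default emulation),
  `sweep_boxes()`, `relative_box_size()`, `write_docking_config()`.
* **Pose evaluation** — heavy-atom RMSD without superposition,
  distance-cutoff contact recovery at atom-pair and residue granularity.
* **Screening metrics** — EF<sup>1%</sup>/EF<sup>10%</sup>, BEDROC20,
  rank-based enrichment AUC, ACT-50%, Mann–Whitney U and Wilcoxon
  signed-rank tests with exact small-sample enumeration.
* **Benchmark harness** — synthetic ligands/complexes/libraries, a mock
  docking backend, `run_ratio_sweep()` and `compare_protocols()`.

## Worked example

```r
library(dockboxr)

# a query ligand and a (predicted) pocket center
lig <- synth_ligand(20, seed = 42)
pocket <- pocket_spec(c(12, 4, -3), source = "predicted")

rg <- radius_of_gyration(lig)
box <- optimized_box(rg, pocket)
box
#> docking_box [optimized]
#>   center:   12.000    4.000   -3.000
#>   size:      7.427    7.427    7.427

relative_box_size(rg, box)
#> [1] 0.35

# the default protocol needs the bound pose instead, and is never below 22.5 A
default_box(lig, seed = 1)$size
#> [1] 22.5 22.5 22.5
```

The optimized edge 7.427 Å is 2.857 × the ligand's Rg of 2.599 Å — a
compound-sized cube rather than the 22.5 Å default floor (11,391 Å³, about
28× the volume here). Screening results are scored the same way
regardless of how the boxes were made:

```r
lib <- synth_ranked_library(n_actives = 100, n_decoys = 5000,
                            mean_active = -10.5, sd = 1.5, seed = 7)
metric_report(lib)
#>   ef_1pct ef_10pct  bedroc20      auc      act50
#> 1      19      6.3 0.4831947 0.878738 0.05588235
```

An EF<sup>1%</sup> of 19 means actives are 19× over-represented in the
top 1% of the ranking relative to chance; AUC 0.879 is the probability an
active outscores a decoy; ACT-50% of 0.056 says half the actives sit in
the best-scoring 5.6% of the library.

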