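---
title: "Sizing docking boxes from the ligand radius of gyration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing docking boxes from the ligand radius of gyration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockboxr)
```

## The model

A docking engine searches an axis-aligned box for low-energy ligand
placements. The box is a genuine model parameter: too narrow and the
correct binding mode cannot be contained (a *sampling failure*), too wide
and the scoring function is given so many irrelevant placements that one of
them outranks the native mode (a *scoring failure*). `dockboxr` implements
three box constructions:

* **Optimized** — a cube centered on the pocket with edge

  $$\mathrm{edge} = R_g / 0.35 = 2.857 \times R_g,
  \qquad
  R_g = \sqrt{\tfrac{1}{N}\sum_{k=1}^{N}\lvert \vec r_k - \vec r_{\mathrm{center}}\rvert^2},$$

  where the sum runs over the $N$ heavy atoms of the query compound and
  $\vec r_{\mathrm{center}}$ is their unweighted geometric center. The
  $1/N$ form makes the descriptor geometric, not mass-weighted, so
  `radius_of_gyration()` applies no atomic masses and excludes hydrogens.
  The constant is stored once as the ratio 0.35; the familiar multiplier
  2.857 is derived from it (`1/0.35`), never rounded twice.

* **Default** — the stock Vina-style protocol for when a bound ligand pose
  is available: bounding box of the pose, +10 Å per dimension applied
  symmetrically (5 Å per side), then per dimension a fair coin picks one
  side to extend by a further 5 Å (the center shifts ±2.5 Å), and finally
  any edge under 22.5 Å is expanded to exactly 22.5 Å. Edge lengths are
  therefore deterministic, `max(extent + 15, 22.5)`; only the center is
  random.

* **Sweep** — a grid of cubes (default edges 2–36 Å in 2 Å steps) around
  one pocket, used to map accuracy as a function of the *relative box
  size* $R_g/\mathrm{edge}$.

### Numerical and dialect choices

The published description of the default protocol does not say whether the
initial +10 Å is symmetric, nor whether the 22.5 Å floor expansion may move
the center. We apply the +10 Å symmetrically and keep the floor expansion
symmetric about the current (already randomly shifted) center: this
reproduces the documented total of +15 Å per dimension and the randomized
center without compounding the random shift. The three coin flips are drawn
in x, y, z order from a seeded generator, so a seed fully reproduces a box.
The pocket-prediction success criterion is strict (`distance < 8` Å; a tie
at exactly 8 fails). Contact distances use a closed ball
(`distance <= cutoff`).

The pose-randomization step used before docking into predicted pockets
(`random_reorientation()`) draws rotations Haar-uniformly over SO(3) via
the uniform unit-quaternion construction
$q = (\sqrt{1-u_1}\sin 2\pi u_2,\; \sqrt{1-u_1}\cos 2\pi u_2,\;
\sqrt{u_1}\sin 2\pi u_3,\; \sqrt{u_1}\cos 2\pi u_3)$ with
$u_i \sim U(0,1)$, applied about the conformer's geometric center.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| Rg-to-edge ratio | 0.35 | – | accuracy optimum of the box-edge sweep; fixed constant of the optimized protocol |
| default-box floor | 22.5 | Å | minimum edge of the emulated stock protocol |
| sweep grid | 2–36 by 2 | Å | fine-grained cubic edge scan |
| contact cutoff | 4.5 | Å | heavy-atom proximity defining contacts; configurable (see below) |
| pocket success | 8 | Å | predicted-vs-experimental center distance threshold |
| curation windows | 6–100 atoms, 50–600 residues | – | benchmark inclusion rules, read as inclusive ranges |
| BEDROC α | 20 | – | concentrates ≈80% of the rank weight in the top 8% |

The contact definition deserves a note: reference pipelines identify
specific protein–ligand contacts with surface-complementarity programs
whose exact algorithm is not reproducible from their descriptions. We use
a heavy-atom distance cutoff as the documented approximation and expose the
cutoff so users can calibrate it against their contact program of choice;
4.5 Å is a package default, not a literature constant.

Two further deliberate scope choices: covalent attachment of a ligand is an
input flag (it comes from database annotation; inferring it from geometry
would be guesswork), and conformer generation is delegated — any supplied
conformer ensemble is accepted, with a `rotamer_hook` seam for external
generators, because the force field behind a "low-energy conformer" is not
part of this package's model.

## Evaluation stack

Pose accuracy is scored in the receptor frame: heavy-atom RMSD **without
superposition** (placement error is part of the signal), the fraction of
recovered binding residues (residue granularity, all atoms of a residue
equivalent) and of recovered specific contacts (atom-pair granularity).
Correspondence is positional; no symmetry correction is attempted, so
highly symmetric ligands can overestimate RMSD — a documented limitation.

Ranking quality uses the standard early-recognition battery. The
enrichment factor at fraction $f$ is the normalized ratio
$(\mathrm{hits}/k)\,/\,(n_{\mathrm{act}}/N)$ with $k=\lceil fN\rceil$ — the
normalized form is the only one consistent with benchmark values near 8
at 1%. "Area under the enrichment curve" is implemented as the rank-based
ROC AUC (probability an active outranks a decoy, ties ½), whose 0.5 random
baseline matches reported values around 0.69; an accumulation-curve
variant would be a different rank functional and is not provided. ACT-50%
uses a ceiling for the required active count. Ties at a top-set boundary
resolve in stable sorted order.

The two nonparametric tests are implemented with midrank ties, exact
enumeration at small sizes (all $\binom{n}{n_a}$ rank assignments for
Mann–Whitney up to $n\le12$; all $2^n$ sign patterns for the signed-rank
test up to $n\le15$) and a tie-corrected normal approximation with
continuity correction above. The enumeration bounds keep the exact paths in
the millisecond range; at the handover sizes the two routes agree to well
under 0.02 in two-sided p.

## The synthetic harness

`synth_ligand()` builds toy compounds as self-avoiding fixed-step chains
(1.5 Å steps, rejection within 80% of a step), which gives the one property
the fixtures need — Rg grows with heavy-atom count. `synth_complex()`
surrounds the native pose with single-atom pseudo-residues, half anchored
3.5 Å off actual ligand atoms so native contacts exist at the default
cutoff by construction. `synth_ranked_library()` draws scores from two
Normal distributions (defaults: actives at −8.70, decoys at −7.85, common
sd 2.1), emulating pooled affinity-score benchmarks with a planted
separation.

`mock_dock()` is an engineered stand-in for a docking engine, and we are
explicit about what it is not: it has no energy model. It samples rigid
placements — uniform orientation, then a center uniform over the positions
at which that orientation fits inside the box — and scores each by its RMSD
to the native pose plus Gaussian noise proportional to the box edge. The
two failure modes are therefore built in: orientations that cannot fit are
rejected (tight boxes make the native mode unreachable and force distorted
placements; hopeless boxes return nothing), and wide boxes drown the
RMSD funnel in noise. `run_ratio_sweep()` drives the full design — dock
every complex at every sweep edge, evaluate top poses, bin by relative box
size (bins of 0.1 by default), average per bin — with per-(complex, edge)
seeds derived from one master seed so any sub-sweep reproduces in
isolation.

Failed points — boxes that could not contain the ligand in any orientation
— are recorded per (complex, edge) point, and the curve reports per-bin
means over the successful dockings together with the failure counts.
When locating the curve's optimum (`sweep_optimum()`), however, failures
are not dropped: a docking that returns nothing has an unreachable native
mode, which is unbounded RMSD and zero contact recovery, so ratio bins
where every attempt failed enter the optimum search as worst-case
outcomes. Averaging only survivors at a box size where most dockings fail
would be survivorship bias — a box that fails nine ligands out of ten is
not a good box because the tenth happened to fit snugly. An optimum is
called *interior* when it falls strictly between the first and last ratio
bin of the full grid: quality must degrade toward generous boxes and
collapse at infeasible ones.

The backend seam in `run_ratio_sweep()` is a callable
`(complex, box, seed) -> ranked poses`: the complex object carries
receptor, ligand and native pose together, because a mock scored by
native-pose RMSD needs the native coordinates, and a real-engine adapter
needs receptor and ligand files anyway. Failures are recorded per point
and excluded from bin means, never fatal.

### What passing tests do and do not show

The harness reproduces the *shape* of the box-size experiment on synthetic
data: a U-shaped mean-RMSD curve and inverted-U contact-recovery curves in
relative box size, with an interior optimum — checked over 50 replicate
sweeps of 20 complexes (chain lengths 10–14) in the test suite. Because the
mock's score is not a physical energy, the *location* of its optimum is not
asserted to be 0.35, and nothing about real Vina accuracy follows from
these tests; they certify the sweep/evaluation machinery, the experimental
design, and the statistics on top of it. Likewise the synthetic libraries
are exchangeable Normal draws: they contain no target structure, no
chemotype clustering and no score ties, so they validate the metric
implementations rather than any screening claim. Benchmark-scale aggregate
numbers (means over thousands of complexes, per-target win fractions on
real screening data) require the real datasets plus a real docking engine
and are out of scope by design.

### Problem sizes

Default test-suite sizes were chosen to keep every property estimable with
comfortable margins on a single CPU: sweeps use 20 complexes × 18 edges ×
50 placements, replicated 50×; enumeration oracles run to $n=14$ (rank
assignments), $n=17$ (sign patterns) and $N=200$ (all-pairs AUC); Monte
Carlo baselines use 10,000 shuffles. The NADP example conformer shipped in
`inst/extdata/` was generated with a distance-geometry embedding
(ETKDG, fixed seed) followed by MMFF minimization and is labelled
`_generated` — it stands in for an unpublished reference conformer, so the
case-study check is advisory (±1.5 Å on the box edge).

## Known limitations

* No symmetry-aware RMSD; no superposition option.
* Contact definition is a distance cutoff, not a surface-complementarity
  algorithm.
* PDBQT support is coordinate extraction only — charges, atom types and
  torsion trees are never interpreted, and PDBQT is never written.
* The mock backend is rigid-body; ligand flexibility (and hence
  conformer-dependent sampling failure) is not modelled.
* `synth_ranked_library()` uses a single common sd for both classes.
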