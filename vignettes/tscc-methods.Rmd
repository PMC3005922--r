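---
title: "Two-stage combinatorial clustering of docked poses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage combinatorial clustering of docked poses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscc)
```

## The problem

Structure-based virtual screening docks thousands of compounds into a
receptor and ranks them by a scoring function. The top of that ranking is
noisy: chemically redundant compounds pile up, and numerically good scores
can hide physically implausible placements. Post-screening analysis
therefore groups the docked poses before anything is sent to a bioassay.
`tscc` implements a two-stage grouping:

1. **Interaction clustering.** Every docked pose is converted into a
   real-valued *interaction profile* indexed by the binding-site atoms:
   entry $E_j$ is the energy protein atom $j$ receives from the whole
   ligand. Poses are clustered on these profiles, so a cluster is a
   *binding mode* — a set of compounds that touch the same protein atoms
   with similar strength — rather than a set of compounds with similar
   coordinates (as an RMSD criterion would give).
2. **Structure clustering.** Within each binding-mode cluster, compounds
   are re-clustered by 2D atom-pair topology, and the lowest docked-energy
   member of every structural sub-cluster is selected as that sub-cluster's
   representative for follow-up.

The combination answers two different questions in sequence: *how* does a
compound bind (stage 1), and *which chemotypes* bind that way (stage 2).

## Stage 1: the interaction profile

For binding-site atom $j$ and a pose with ligand heavy atoms $i$,

$$E_j = \sum_{i \in \mathrm{lig}} \left[ f\!\left(r_{ij};
V_1,\dots,V_6^{(B_{ij})}\right) + \frac{332.0\, q_i q_j}{r_{ij}} \right]$$

where $r_{ij}$ is the Euclidean distance in &Aring;ngstr&ouml;m, $q_i, q_j$ are
formal charges (332.0 converts $e^2/\mathrm{\AA}$ to kcal/mol), and
$B_{ij}$ selects one of two parameter sets — *hydrogen bond* when one atom
of the pair can donate and the other accept, *steric* otherwise. $f$ is a
piecewise-linear potential (PLP): a contact penalty $V_5$ at $r = 0$
falling to zero at $V_1$, an attractive well of depth $V_6$ on
$[V_2, V_3]$, and zero beyond $V_4$, with linear segments between.

Defaults ship in `inst/extdata/plp_params.json` and follow the published
GEMDOCK/PLP convention:

| class  | $V_1$ | $V_2$ | $V_3$ | $V_4$ | $V_5$ | $V_6$ |
|--------|------:|------:|------:|------:|------:|------:|
| hbond  | 2.3   | 2.6   | 3.1   | 3.6   | 20    | -2.5  |
| steric | 3.3   | 3.6   | 4.5   | 6.0   | 20    | -0.4  |

(distances in &Aring;, energies in kcal/mol). All six values are overridable
per class; the file is the single source of truth so the parametrisation is
auditable without touching code.

Design points that were genuinely open, and how they were fixed:

* **Electrostatics inside the profile.** The Coulomb term is summed into
  $E_j$ by default (`include_electrostatics = FALSE` disables it). It is
  applied only between pairs where *both* formal charges are nonzero, with
  a hard 12 &Aring; cutoff — there is no universal convention for the cutoff,
  and 12 &Aring; comfortably exceeds the PLP range so the profile support is
  still dominated by contacts.
* **Donor/acceptor typing without hydrogens.** Inputs are heavy-atom only
  (hydrogens are stripped on load), so donor character is inferred: for
  ligands from the bond graph (an N below its valence carries implicit H
  and donates; a singly bonded neutral O is a hydroxyl and is both donor
  and acceptor; carbonyl, ether and anionic O, and S, accept), and for
  receptors from a residue/atom-name table encoding standard amino-acid
  chemistry. The table is deterministic, so profiles are reproducible;
  chemically exotic receptor atoms fall back to element rules.
* **Binding site.** Residue-level membership: every residue with at least
  one atom within 10 &Aring; (default; the common 8–12 &Aring; pocket range) of
  any reference-ligand atom, keeping whole residues so profile columns
  correspond to chemically meaningful units. When no crystallographic
  ligand is available, `run_tscc()` anchors the site on the union of all
  docked poses.
* **Involved atoms.** Site atoms with $|E_j| < \varepsilon$ (default
  $10^{-6}$ kcal/mol) across *all* poses carry no information and their
  columns are dropped before distance computation; retained values are
  never modified.

Profiles are compared with **correlation distance** $d = 1 - r$ (Pearson,
sample standard deviation), range $[0, 2]$. Correlation, not Euclidean
distance, is the right comparison here: it asks whether two poses
distribute their interaction strength over the same protein atoms, not
whether their total energies match. Zero-variance profiles make $r$
undefined; the package fixes $d = 0$ for two identical constant vectors
and $d = 1$ otherwise, keeping the clustering total. One-ulp excursions of
`cor()` are clamped so the metric range is exact.

## Stage 2: atom-pair structure clustering

Each compound's heavy-atom bond graph is encoded as a binary atom-pair
descriptor: bit (type$_a$, type$_b$, $k$) is set when some atom pair of
those types lies at shortest bond-path distance $k$. With the 10-letter
element alphabet `C N O S P F Cl Br I X` and 15 distance bins this gives
$\binom{10+1}{2} \times 15 = 55 \times 15 = 825$ bits. Two conventions are
the package's own (the descriptor family does not fix them): paths longer
than 15 bonds fold into bin 15 rather than being discarded, and presence
is recorded rather than counts. Columns zero across the whole compound set
are removed, mirroring the involved-atom rule of stage 1.

Descriptors are compared with **Tanimoto distance**
$d = 1 - |X \cap Y| / |X \cup Y|$ on ON bits (two empty fingerprints are
identical objects, $d = 0$), which is a true metric — the triangle
inequality is property-tested on $10^4$ random triples.

## Clustering, cutting, thresholds

Both stages use **UPGMA** (average linkage): the distance between two
clusters is the unweighted mean of all cross-pair leaf distances, and each
merge is recorded at that height. The implementation recomputes cluster
distances from the leaf matrix at every step (exactly the definition, no
Lance–Williams update) and breaks ties by the lexicographically smallest
(min member id, max member id) pair, so results are identical across
platforms and input orderings; `stats::hclust(method = "average")` serves
as an independent cross-check in the test suite. Trees are
`hclust`-compatible, export to Newick with ultrametric branch lengths
(leaf depth = root height / 2), and are cut by removing merges strictly
above a height threshold; flat labels are numbered by smallest member id.

The default cut heights — **0.39** correlation distance for stage 1 and
**0.55** Tanimoto distance for stage 2 — are reference thresholds learned
on known-active compound sets by *maximum discrimination*: sweep a
candidate threshold $t$ over the midpoints of consecutive sorted pooled
pair distances (plus both extremes) and maximise

$$\mathrm{acc}(t) = \frac{\#\{d_\mathrm{intra} < t\} +
\#\{d_\mathrm{inter} \ge t\}}{n_\mathrm{intra} + n_\mathrm{inter}}.$$

The two count terms share one denominator (unbalanced accuracy); whether
the objective should instead balance the classes cannot be settled from
the method's published description, so the unbalanced form is implemented
and named in the report output. Midpoint candidates avoid the boundary
ambiguity of the strict `<` at observed values; the smallest maximising
candidate is returned. `reference_threshold()` re-learns the cut for any
labelled pair-distance sample; the shipped defaults are sensible for
GEMDOCK-like scoring but are data-dependent quantities, not constants of
nature.

Separation quality is validated the way descriptor studies tabulate it: a
pooled-variance two-sided two-sample $t$-test of intra- versus
inter-cluster distances at $\alpha = 0.01$, reporting group means and
sample standard deviations. Degenerate input (zero pooled variance, equal
means) is defined to $t = 0$, $p = 1$.

## Representative selection

Stage 2 runs on every stage-1 cluster by default (`clusters` in
`tscc_config()` restricts it, recovering the common usage of analysing
only the actives-containing cluster). Within each structural sub-cluster
the member with the minimum docked energy is the representative; energy
ties break to the lexicographically smallest pose id. When several poses
of one compound are present, a pre-filter keeps only that compound's
lowest-energy pose, so representatives are compounds, not conformers.

## The synthetic-data generator

Real post-screening inputs (a docked compound library against a protein
target) cannot ship with a package, so `synthdata` builds deterministic
stand-ins that exercise every code path:

* **Receptor:** `n_site_atoms` (default 32) point atoms on an 8 &Aring;
  sphere (golden-spiral layout, seeded 0.15 &Aring; radial jitter), grouped
  into 4-atom pseudo-residues, elements cycling C/N/O/S so donor,
  acceptor, both and nonpolar classes all occur, with one +1/-1 charge
  pair.
* **Poses:** each of `n_modes` (default 2) binding modes anchors ligands
  at a distinct angular position 3 &Aring; from the pocket centre and owns a
  fixed direction template; a compound's atoms grow along that template at
  1.5 &Aring; bond length, clamped to a 2 &Aring; ball (a binding mode *is* a
  conserved, clash-free placement). Per-pose isotropic jitter
  `noise_sigma` (default 0.25 &Aring;, roughly crystallographic coordinate
  uncertainty) and uniform docked energies on $[-12, -6]$ kcal/mol
  complete the pose. Odd modes dock a protonated-amine form, even modes a
  neutral form: protonation is a compound property, and a charge column
  common to *every* pose would dominate the centred correlation and mask
  the geometric signal.
* **Molecule families:** family $k$ shares a 6-ring scaffold with a
  marker heteroatom at ring positions 1 and 4 and a 3-carbon tail;
  members differ by 1–3 single-atom decorations. Within-family Tanimoto
  distances are systematically below across-family ones, which the tests
  measure rather than assume.

Everything derives from one integer seed through a helper that saves and
restores the global RNG state, so generation is reproducible and
side-effect free. What the generator deliberately does **not** emulate:
force-field-valid geometry, conformational strain, solvation, binding-site
flexibility, or the score noise of a real docking engine. Passing the
end-to-end tests therefore demonstrates that the pipeline's machinery is
correct and that it recovers planted structure under controlled noise —
not that the default thresholds are optimal for any particular real
target; those should be re-learned per target with
`reference_threshold()`.

## Numerical choices and degenerate inputs

* PLP continuity at all four breakpoints is asserted to $10^{-9}$; the
  minimum equals $V_6$ exactly on $[V_2, V_3]$.
* Overlapping atoms ($r_{ij} = 0$) abort with an error naming the pair —
  a zero distance means broken input, not physics.
* Profile computation is invariant to atom reordering and to rigid
  translation of pose and site together (tested to $10^{-9}$).
* UPGMA merge heights are non-decreasing (guaranteed for average linkage
  on true distance matrices) which makes the height cut well defined.
* File formats are plain text: PDB (first model, blank/'A' altLoc, formal
  charges in columns 79–80), SDF V2000 (`M CHG` supported), MOL2 via
  OpenBabel conversion with 3D coordinates preserved. Readers never let a
  hydrogen atom through.

## Problem sizes in the shipped tests

The test and acceptance runs use the generator defaults: 40 poses
(2 modes × 2 families × 10 compounds) against a 32-atom pocket, 100
random 6-leaf matrices for the UPGMA oracle, $10^4$ random cases per
metric law, and 50 + 50 samples for threshold learning — sizes chosen so
the full suite completes in seconds while every oracle comparison remains
exhaustive at its scale.

## Known limitations

* The PLP parameter defaults are a published-convention choice, not a
  refit; quantitative energies should not be compared across scoring
  functions.
* Atom typing for the descriptor is element-level. Hybridisation-aware
  typing (the classic atom-pair formulation) would discriminate, e.g.,
  aromatic from aliphatic carbon, at the cost of a larger, sparser bit
  space; with `T` types the space is `T(T+1)/2 * n_bins`.
* Receptor donor/acceptor typing is table-driven and ignores protonation
  states (HIS tautomers are classed "both").
* UPGMA is $O(n^3)$ in the naive-recompute form used here; it is exact
  and deterministic, and comfortable to a few thousand poses, but a
  Lance–Williams update would be needed far beyond that.
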