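---
title: "Contact-constrained rigid-body docking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-constrained rigid-body docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condock)
```

## The problem and the approach

Rigid-body docking predicts the structure of a two-protein complex from the
structures of its separate partners. The geometric filtering stage scans a
very large space of relative placements and keeps a small candidate set; if
no near-native placement survives filtering, no scoring function can rescue
the prediction afterwards. condock attacks the filtering stage from sequence
data: when homologs of both partners exist across many organisms, residues
that touch across the interface are under joint evolutionary pressure —
conservation, correlated substitutions, residue complementarity — that
leaves a statistical fingerprint in the paired multiple sequence alignments
(MSAs). The package

1. ranks candidate inter-protein residue pairs by a Naive Bayes contact
   score computed from MSA- and surface-derived descriptors, and
2. turns each top-ranked pair into a maximum-distance constraint that prunes
   the translational docking scan, so that each constrained run is small and
   the union of runs over, say, 100 predicted contacts retains many more
   acceptable models than one unconstrained run of the same total size.

Individual contact predictions are noisy; the design bet is that among the
top ~100 ranked pairs at least one is a true contact, and constraint
propagation makes scanning all 100 cheap.

## Data preparation model

**True contacts.** Two residues, one per partner, are in contact when their
closest heavy (non-hydrogen) atoms are within 5 Å — the CAPRI criterion.
`find_contacts()` implements this both across partners (labels) and within a
partner (spatial neighborhoods).

**Candidate residues.** Only surface residues can touch the partner.
`compute_residue_areas()` estimates solvent-accessible surface area by
rolling-probe point sampling (Shrake–Rupley): each heavy atom is covered
with 960 quasi-uniform points at radius vdW + 1.4 Å (a water probe) and
points inside any neighboring expanded sphere are buried. vdW radii: C 1.7,
N 1.55, O 1.52, S/P 1.8 Å; other elements fall back to 1.7 Å with a
warning. Side-chain area sums all atoms except backbone N, CA, C, O, so
glycine's side-chain area is 0 by definition. A residue is a candidate when
its full exposed area is strictly greater than the cutoff, 38 Å² by
default. `select_area_cutoff()` reproduces the cutoff-selection rule: over a
grid of cutoffs it minimizes (mean candidate pairs / minimum surviving true
contacts over complexes) × (fraction of true contacts lost in the complex
with the fewest true contacts). Note a degenerate property of this literal
product: any cutoff that loses zero true contacts scores 0, so the rule is
only informative on surveys where every grid point loses something in the
smallest complex; ties resolve toward the smaller cutoff, which keeps more
true contacts.

**Paired alignments.** `pair_rows_by_organism()` matches MSA rows across
the two partners by source organism, the premise being that homologs from
the same organism interact the way the query pair does. When an organism has
several rows, the row with the highest ungapped identity to that
alignment's query wins (ties: first row). The two query rows are always
paired.

## Descriptors and features

For every candidate pair, 17 base descriptors are computed
(`descriptor_registry()`): max/min full-residue and side-chain exposed
areas; max/min per-residue Gonnet substitution scores (mean Gonnet score of
the query amino acid against its column across matched rows, gaps skipped)
and the same relative to the chain average; four residue-pair interaction
scores averaged over matched row pairs (two volume-normalized contact
scores, all-atom and α-carbon contact propensities); max/min column gap
fraction; max/min column gap share (column gaps over the alignment's total
gaps); and a pairwise co-occurrence score — the log-odds of the query
amino-acid pair's joint frequency over matched rows against the product of
the column marginals, with +1 pseudocounts, deliberately ignoring sequence
neighbours.

Two aggregation schemes extend each descriptor over the spatial
neighborhood of a residue (the residue plus all candidate-set residues in
intra-protein contact with it at 5 Å): *all-to-one* averages the descriptor
from every neighbor of one residue to the specific residue of the other
partner, symmetrized over both directions as one mean over the distinct
index pairs; *all-to-all* averages over the full neighborhood product. This
yields 51 features. Features are scaled to span [−1, 1] on the training
set (`fit_feature_scaler()`); test values outside that range are not
clipped. Descriptors that cannot be computed (e.g. a non-standard residue
with no substitution scores) are imputed with the table mean and recorded
in the `imputed` attribute.

The Gonnet matrix ships with the package as a plain-text 20×20 table. The
four pair-score tables are **synthetic stand-ins** constructed
deterministically from the Kyte–Doolittle hydropathy scale, side-chain
charges and mean residue volumes; they have the right shape and symmetry
but are not the published propensity tables, which are not reproducible
from text sources. `load_score_matrix()` lets users substitute literature
tables; absolute feature values (and therefore exact reproduction of the
original classifier) depend on that substitution.

## The classifier

A binary Naive Bayes classifier over equal-width-discretized (EWD)
features. The bin count for class *k* follows the Rice rule,
2·N_k^(1/3) rounded half away from zero — with realistic candidate sets
this is on the order of 200 bins for the abundant non-contact class and 30
for the contact class. Edges are computed per class over that class's
training values (the two classes have different sample sizes, hence
different resolutions); scoring values outside a class's range clamps into
the boundary bin. Conditional probabilities use +1 Laplace smoothing,
(count + 1)/(N_k + n_k), keeping every logarithm finite; priors are pooled
class frequencies; all arithmetic is sums of natural logs rather than
probability products to avoid round-off. The contact score is the
difference of unnormalized log posteriors, and ties in the ranking break by
the residue identifiers for reproducibility.

One practical consequence of clamping worth knowing when interpreting
scores: a value far outside a class's training range receives the boundary
bin's full probability mass, so "far away" is never penalized beyond the
boundary bin. Discrimination therefore comes from where densities differ
within the shared range, not from range separation.

**R-precision.** Ranking quality per complex is precision within the top
R positions, R being that complex's number of true contacts. When not even
one true contact makes the top R, the value is 1 − highestTrue/R instead —
a negative number measuring how badly the classifier missed. The
cross-validation harness (`cross_validate()`) partitions complexes (never
pairs) into folds — 5 by default, seeded shuffle of sorted complex ids,
default seed 75 recorded in the output — and macro-averages the per-complex
values. Null behaviour of the extended metric: with few true contacts per
complex the negative branch dominates random rankings, so its null mean is
well below the prevalence; it approaches the prevalence only when R is
large relative to the ranking length.

## Feature selection

`beam_forward_search()` is forward sequential search that retains the best
N subsets per size instead of one: all single features are evaluated, the
top N retained, each retained subset is extended by every unused feature,
deduplicated order-insensitively, re-evaluated by cross-validated mean
R-precision, and so on. The retention width N is configurable (default 10;
the width used in the original work is not recoverable). With N = 1 the
algorithm is classic greedy forward selection; with N at least the number
of subsets of each size it is exhaustive — both limits are exercised in the
tests. Score ties break lexicographically; the best overall subset takes
the smallest size among score ties. Per-subset scores are cached; caching
cannot change results because the CV folds are fixed per search.

## Constrained docking

The docking stage is a simplified grid-based rigid-body search in the
spirit of constraint-propagating soft-docking programs; it does not
reproduce any published scoring function beyond surface-contact counting.

* `digitize()` maps a structure onto a cubic grid (default 1 Å): *core*
  cells have centers within the vdW radius of some heavy atom, *surface*
  cells within vdW + 1.5 Å but not core.
* `search_translations()` scores every lattice translation of the ligand
  grid by the number of overlapping surface–surface cell pairs, discarding
  translations with more than `core_overlap_tol` (default 0) core–core
  overlaps. The scan is implemented as a cross-correlation — every surface
  cell pair votes for the translation superimposing it — which equals
  brute-force enumeration exactly (tested on small lattices).
* `prune_with_constraint()` converts a residue-pair constraint into a
  lattice ball: any translation that can satisfy "residues within
  max_dist" must place the ligand residue centroid within max_dist + ρ_A +
  ρ_B + slack of the receptor residue centroid (ρ = residue
  centroid-to-atom radius). This region is a guaranteed superset of all
  exactly-satisfying translations, so pruning is sound; the slack (default
  3 Å) only widens the region to absorb grid discretization, and candidate
  placements are then verified against the constraint's own max_dist by
  exact atom distances.
* `run_constrained_docking()` repeats the pruned scan per rotation and per
  constraint, keeping the best `models_per_constraint` placements per
  constraint (ties: rotation index, then tz, ty, tx).
  `sample_across_constraints()` retains a balanced model set — total/k per
  constraint by largest remainder, so 100 constraints at a total of 500
  means 5 models per constraint, 10 for 1000 — deduplicating identical
  placements. Balanced sampling exists because a few wrong constraints with
  high surface scores would otherwise crowd out acceptable models.

Rotation sampling is a deterministic ZYZ Euler grid
(`rotation_grid()`, configurable step) or seeded uniform random rotations.
The package's tests and acceptance runs use the identity rotation
(bound-pose recovery) and small random sets: a full rotational sweep is a
compute-cluster exercise and, as the absolute model counts of any specific
benchmark depend on unpublished sampling settings, only the qualitative
constrained-vs-unconstrained behaviour is testable at desk scale.

## Evaluation

`evaluate_model()` implements the CAPRI-style criteria. Ligand RMSD:
superpose the model on the reference over the larger partner ("receptor",
by residue count, ties by heavy atoms) and measure RMSD over the smaller
partner. Interface RMSD: best-fit RMSD over reference-interface residues
(within 5 Å of the other partner). Superposition uses Kabsch SVD with a
proper-rotation correction; the atom set is Cα by default, falling back to
all shared heavy atoms for pseudo-atom toys. A model is acceptable iff
ligand RMSD < 10 Å AND interface RMSD < 4 Å, both strict; the official
CAPRI tier system differs and is out of scope. The *gain* of constraints is
the total acceptable models with constraints divided by the total without,
summed over complexes before dividing — `compute_gain()` — and the package
ships the per-complex acceptable-model counts of a published 28-complex
benchmark (`benchmark_counts()`) as a plain-text table from which the gain
statistics are recomputed, never stored.

## Synthetic data: what it emulates, and what it does not

All tests run on seeded generators; nothing is downloaded.

* `make_toy_complex()` builds two solid partners from dense 3×3×3
  pseudo-atom cubes (1 Å atom spacing, single 1.7 Å vdW radius) on a
  4.5 Å residue lattice, with a corrugated interface: each interface site
  carries a seeded depth offset shared by both partners, designated contact
  sites protrude so their closest atoms sit at exactly 4.5 Å (inside the
  5 Å criterion), and all other sites are recessed past it. The dense
  packing matters: sparse "blob" toys let a rigid ligand interdigitate
  into inter-residue voids — placements impossible for real packed proteins
  yet invisible to a 1 Å center-point core test — and the corrugation gives
  the true pose a genuine surface-complementarity funnel. Atom pairs across
  partners stay above ~3.9 Å, above the ~3.4 Å limit at which two 1.7 Å
  cores can share a grid cell, so hard-core docking is clash-free at the
  true pose by construction.
* `make_synthetic_alignments()` plants the coevolution signal contact
  prediction assumes: per organism, designated contact column pairs
  co-substitute (via a fixed amino-acid bijection) with configurable
  probability, everything else mutates independently; gaps are sprinkled at
  a configurable rate; query rows always degap to the structure sequences.
  Defaults (30 organisms, substitution rate 0.1, coevolution 0.8, gap rate
  0.05) mirror a modest ortholog set with strong interface coupling.
* `make_feature_table()` draws non-contacts from standard normals and
  shifts contacts by a configurable amount on informative features —
  the abstract version of "some descriptors carry signal".

What passing these tests does **not** show: real MSAs have phylogenetic
correlation between rows (not i.i.d. organisms), alignment errors, and
paralog confusion; real structures have heterogeneous atom radii, missing
residues and conformational change between unbound and bound forms; and
real interface complementarity is far subtler than corrugated slabs.
Results on the generators validate the machinery, not benchmark-level
accuracy.

## Numerical choices and degenerate inputs

* Rounding in the Rice rule is half-away-from-zero; bin counts never drop
  below 1. Degenerate all-equal features get an epsilon-expanded single
  bin.
* Altloc resolution keeps the highest occupancy, then file order; hydrogens
  (H/D) are dropped before anything else sees the structure.
* Empty-region scans, singleton neighborhoods, constant features and
  single-row (query-only) alignments all degrade gracefully and are
  tested.
* Problem sizes in the test-suite and acceptance script (toys of 8+8
  residues at 27 atoms each, feature tables of 10⁴ pairs, 20-seed
  repetitions, beam searches over 8-feature pools) were chosen so the full
  pipeline — including its brute-force oracles — runs comfortably on a
  laptop-class single core.
* Planted-pose recovery runs keep 50 models per constraint, the deepest
  per-constraint retention implied by balanced sampling at a 5000-model
  total over 100 constraints.

## Known limitations

* The four pair-score tables are synthetic stand-ins (see above); with
  them, feature values are internally consistent but not comparable to the
  original implementation's.
* The enumerable descriptor registry has 17 entries (51 features); the
  original descriptor set was larger by four descriptors whose identity is
  not recoverable, so the registry is pluggable rather than fixed.
* SASA probe radius, point density and vdW radii are stated defaults, not
  recovered constants; absolute areas, and hence the effective bite of the
  38 Å² cutoff, can differ from other implementations.
* The docking stage scores surface complementarity only — no
  electrostatics, side-chain softness, or flexibility — and its absolute
  model counts are not comparable to any published benchmark table.
* Multi-chain partners are handled one mapped chain per alignment;
  map a chain per partner when building feature tables.
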