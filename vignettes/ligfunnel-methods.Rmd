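---
title: "Methods: a multi-step ligand-based virtual screening funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-step ligand-based virtual screening funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large vendor libraries (10^5–10^6 compounds) cannot be assayed against a
receptor target exhaustively. Ligand-based virtual screening funnels
exploit what is already known about a target — here, a GPCR with a body of
published antagonist affinities — to shrink the library to a shortlist a
medicinal chemist can inspect. `ligfunnel` implements one such funnel as a
reusable, fully tested library: activity curation, two trainable
classifiers (a dense network on circular fingerprints and a
graph-convolutional "neural fingerprint" network) combined by consensus, a
ligand-based 3D pharmacophore filter with k-of-n partial matching, a
cascade percentage filter over externally produced docking scores, and
early-recognition enrichment metrics to validate each stage. Everything
downstream of file input runs on synthetic, planted-signal data as well,
so the whole funnel is exercisable without any proprietary dataset or
docking engine.

## Data curation

Affinities arrive as pKi = −log10(Ki). Compounds with pKi strictly above 8
(Ki < 10 nM) are labeled active; strictly below 6 (Ki > 1 µM) inactive;
the mid-range — including the boundaries exactly — is excluded from model
training. Strict inequalities are a deliberate reading: a compound sitting
exactly at a threshold carries no class evidence either way. Duplicate ids
keep the median pKi (robust to a single discordant assay).

Splitting is 7:2:1 (train/test/validation) by largest-remainder
apportionment, stratified by label, under a caller-supplied seed. Largest
remainder guarantees the split sizes sum exactly to n and each stratum's
proportions deviate from the global ratio by less than one record.

Representative selection for pharmacophore training clusters potent
actives by average-linkage hierarchical clustering on (1 − Tanimoto)
distance and takes each cluster's medoid (highest mean intra-cluster
similarity). Decoy selection is DUD-E-flavored: a pool candidate is
accepted when it sits inside every property window (MW ±25 Da, logP ±1,
HBD ±1, HBA ±1, rotatable bonds ±1 — all configurable) of at least one
active while its ECFP4 Tanimoto to *every* active stays ≤ 0.75, with at
most 30 decoys charged per active. Candidates are processed in id order so
the result is invariant to pool ordering.

## The molecule layer

No cheminformatics toolkit is assumed: the package carries its own
molecular graph with a SMILES reader/writer covering the organic subset
(B, C, N, O, P, S, halogens), aromatic lowercase notation, charges,
explicit H counts, branches and ring closures. Implicit hydrogens follow
standard valences; aromatic atoms use the σ-count + 1 convention so bare
`n` carries no hydrogen and ring-fusion carbons get none. The canonical
writer uses Morgan-style partition refinement with deterministic
tie-breaking; atoms still tied after refinement are treated as
automorphic — the standard heuristic, property-tested over random atom
permutations rather than proven. Stereochemistry is read and discarded:
the whole pipeline is topological except for the pharmacophore stage,
which consumes externally supplied 3D conformers.

logP is a coarse atom-contribution estimate (aromatic vs aliphatic carbon
distinguished, −0.3 per polar hydrogen). It is used only inside ±windows
against other compounds computed the same way, where internal consistency
matters and absolute accuracy does not.

## Fingerprints

`ecfp4()` hashes circular atom environments to radius 2 (diameter 4): the
initial invariant encodes element, degree, H count, charge, aromaticity
and ring membership; two iterations fold in sorted (bond, neighbor)
multisets; identifiers from all radii are folded onto 2048 bits
(configurable). Bit positions are implementation-specific — all similarity
work and every test operates on Tanimoto values and invariances, never on
particular bit indices. Tanimoto is |A∩B|/|A∪B| with 0/0 defined as 0;
novelty of a candidate is its maximum Tanimoto to a reference active set
(lower = more novel).

## Classifiers

Both networks output a probability through a sigmoid, train with binary
cross-entropy plus L2 (default 1e-4), Adam (default learning rate 0.001),
and early stopping on validation loss (patience 20, best weights kept).
Training is a pure function of the seed.

* **Dense network** on fingerprint bit vectors: ReLU hidden layers
  (default 512 and 128 wide) with dropout 0.25, default batch size 300.
* **Neural-fingerprint network** on the molecular graph: each of
  `nfp_depth` (default 2) rounds updates atom states by aggregating
  neighbor states plus summed incident bond features through a ReLU layer;
  each round contributes a softmax-sparsified projection of the atom
  states, summed over atoms, to a learned fingerprint (default length
  128), followed by a small ReLU head (default 64). Summation over atoms
  makes predictions exactly invariant to atom numbering. Default batch
  size 350.

The layer widths, dropout rate, epoch budget and loss are package
defaults chosen for desk-scale CPU training on ~10^3 compounds; they are
all exposed in `classifier_config()`. Analytic gradients of both
architectures are checked against central finite differences in the test
suite. `batch_size_sweep()` reproduces the model-selection protocol (one
model per batch size, winner by AUC with MCC tie-break).

Evaluation reports sensitivity SE = TP/(TP+FN), specificity
SP = TN/(TN+FP), predictive accuracies Q+ = TP/(TP+FP) and
Q− = TN/(TN+FN), the Matthews correlation coefficient, and AUC by the
Mann–Whitney rank statistic with average ranks on ties. Any zero
denominator is reported as NA, never silently coerced to 0 — on a
degenerate split a missing metric is information, a fake 1.0 is not.

## Enrichment metrics

For a ranked screen of N compounds with A actives at 1-based ranks r_i:

* **EF at fraction f**: the top bin holds `ceiling(f·N)` compounds
  (ceiling guarantees a non-empty bin; with N = 887 and f = 1% the bin is
  9, which reproduces the characteristic discrete EF levels 3.40, 6.80,
  10.20, 13.59 for A = 29). Ties at the bin boundary resolve by the
  screen's stable order.
* **BEDROC(α)**: Truchon–Bayly with the exact min/max normalization (not
  the RIE/RIE_max shortcut); α = 160.9 weights roughly the top 1%. The
  value is clipped to [0,1] to guard floating-point underflow at the
  all-bottom extreme. As α → 0 BEDROC approaches the min-max normalized
  AUAC, which the tests check at α = 1e-3.
* **ROC area**: rank statistic, average ranks on ties (an all-tied screen
  scores exactly 0.5).
* **AUAC**: `1 − mean(r_i/N)`.

Compounds that fail a filter are retained at the bottom of the screen with
score −Inf, so enrichment is computed over the whole library (the
alternative — dropping unmatched actives from N — silently flatters every
metric).

## Pharmacophore modeling

This module is an open re-specification of what proprietary tools do with
undisclosed algorithms; no numerical agreement with any of them is
claimed. Feature perception uses a small documented dictionary: acceptors
(N/O, charge ≤ 0, excluding pyrrole-type NH), donors (N–H/O–H),
hydrophobes (Cl/Br/I atoms, CF3-like groups, runs of ≥ 2 nonaromatic
carbons with only C/halogen neighbors, centroid-placed), aromatic ring
centroids with normals, and charged P/N features.

Hypothesis generation enumerates size-4 and size-5 feature subsets on each
active conformer and hashes each arrangement by its sorted kind multiset
plus binned pairwise distances (bin width 1 Å). An arrangement present in
enough actives becomes a hypothesis: contributors are superposed onto the
first by kind-preserving least-squares (Kabsch), feature centers are the
mean aligned positions, and the score is
`0.7·(actives matched / actives) + 0.3·(1 − meanRMSD / 2 Å)`. Binning can
split near-identical arrangements that straddle a bin edge; the synthetic
world keeps planted distances away from integer edges, and real use can
lower the bin width or jitter-tolerance accordingly — a documented
limitation of distance hashing.

Matching accepts a molecule when at least k of the n hypothesis features
(default k = 4, the "4 of 5" convention) can be assigned to
kind-compatible molecule features such that, after rigid superposition,
every matched feature lies within its tolerance sphere (default 2 Å);
ring normals are additionally checked against a 45° cone when both sides
define one, axially (normals have no preferred sign). Search order is
largest subset first, then lowest RMSD; candidate assignments are pruned
by pairwise distance compatibility before any superposition. The fit
score is `matched_count − RMSD/mean(tolerance)`, and screening ranks by
fit with stable id tie-break.

One geometric consequence worth knowing: a rigid least-squares fit spreads
a single displaced feature's error over all matched points, so a
displacement must comfortably exceed the tolerance budget (not merely the
single-sphere radius) before a k = n match fails. The synthetic decoy
generator displaces its donor arm 8 Å for this reason.

## The funnel

Stage order: classifier consensus (intersection by default — a compound
must be predicted active by both networks), pharmacophore k-of-n filter,
then one `floor(fraction·n)` (minimum 1) percentage filter per externally
supplied docking score table, then a top-K shortlist annotated with
novelty. Docking is consumed, never computed: each cascade stage reads an
(id, score) table from any engine, lower-is-better by convention, with
duplicate ids keeping the best score and unmatched compounds reported and
traced. The final stage accepts an explicit cap because published
campaigns sometimes report a retained count that the stated percentage
does not reproduce. The report carries per-stage in/out counts and a
complete per-compound trace (each library member lands in exactly one
elimination bucket or the shortlist); a stage that eliminates everything
finalizes the report early rather than erroring. The human
visual-inspection step of real campaigns is deliberately replaced by the
configurable top-K plus novelty column.

## The synthetic world

Four generators make every stage testable offline; they encode
statistical structure, not vendor-library realism:

* **Fingerprint datasets**: sparse background bits plus an informative
  block whose bits are drawn from a two-regime mixture (p = 0.5 ± margin,
  default margin 0.35); the label is always the majority-threshold rule
  applied to the realized bits, optionally noise-flipped. The margin is
  the separability knob: at margin 0 the rule's decision boundary sits on
  single-bit differences and a high-capacity network memorizes instead of
  generalizing; 0.35 makes the classes cleanly separable, which is the
  regime the classifier-recovery tests assert. A `null_labels` switch
  yields the no-signal control.
* **Motif libraries**: random aliphatic C/N/O scaffolds; actives carry a
  grafted sulfonamide (`S(N)(=O)=O`) and scaffolds never contain sulfur,
  so a plain substructure search recovers exactly the actives — the
  construction oracle for the graph network.
* **Pharmacophore sets**: rigid toy molecules (benzene ring, carbonyl
  acceptor, amine donor, propyl hydrophobe) whose perceived features sit
  exactly at a stated A/D/H/R quadrilateral (default pairwise distances
  4.3–5.4 Å, away from distance-hash bin edges); decoys displace the
  donor arm. Bond geometry is not physically realistic — only the feature
  geometry is the point. A distance-matrix geometry is accepted and
  embedded by classical scaling; infeasible matrices are rejected.
* **Ranked screens** with actives at prescribed ranks and strictly
  decreasing scores, for exact enrichment arithmetic.

A green test on this world establishes that the machinery recovers
planted signal under its stated assumptions; it says nothing about
performance on real assay data, conformer quality, tautomers or
protonation states (single input structure per compound, by convention).

## Numerical choices

* EF top bin: ceiling; cascade retention: floor with minimum 1
  (conservative shrink). Both documented above.
* Ranking ties: stable sorts keyed by compound id everywhere a tie could
  otherwise depend on input order.
* Undefined metrics: NA, never 0.
* RNG: every stochastic routine takes a seed and runs under a
  save/restore wrapper (`with_seed`), so library calls never perturb the
  caller's RNG stream.
* Degenerate inputs: empty libraries screen to empty results; an empty
  consensus finalizes the funnel early; single-class training sets are
  errors.

## Known limitations

* SMILES coverage is the organic subset without stereochemistry or
  isotopes; exotic elements are rejected loudly.
* Canonicalization relies on the refinement-orbit heuristic (no full
  automorphism search); adversarial highly symmetric graphs could in
  principle defeat it.
* ECFP bit positions, the logP estimate and the feature dictionary are
  internal conventions; cross-toolkit numeric identity is out of scope.
* Conformer generation is upstream: molecules must arrive with 3D
  coordinates for the pharmacophore stage.
* The pharmacophore hash can split borderline arrangements at bin edges;
  see above.
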