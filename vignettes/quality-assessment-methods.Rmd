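---
title: "Equivariant quality assessment of protein structural models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivariant quality assessment of protein structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enqar)
```

# The problem

A predicted protein structure is a hypothesis. Model quality assessment
(QA) estimates, residue by residue, how close that hypothesis is to the
(unknown) true structure, on the lDDT scale: the fraction of local
reference distances (within a 15 Å inclusion radius) reproduced within
0.5, 1, 2 and 4 Å, averaged over the four thresholds. lDDT is
superposition-free, bounded in [0, 1], and local, which makes it a good
per-residue target. The mean over residues is the per-model score.

`enqar` predicts lDDT from the model itself (single-model mode) or from
the model plus five reference predictions with their distograms
(reference mode). Because quality is a geometric property, every feature
and every network operation is built to be invariant (scalars) or
equivariant (coordinates) under rigid motions of the input — nothing the
method reports may depend on how the model happens to be oriented.

# Feature pipeline

## Geometric node descriptors

Three per-residue descriptors characterize the local environment:

* **SASA** (Shrake–Rupley): backbone + Cβ atoms (N 1.55 Å, C 1.70 Å van
  der Waals radii), water probe 1.4 Å, a deterministic Fibonacci sphere
  lattice of 120 points per atom. Deterministic sampling makes results
  exactly reproducible; the lattice is oriented in the structure's
  canonical principal-axes frame (eigenvectors of the coordinate
  covariance; axis signs fixed by the third moment of the projections,
  with a sequence-order fallback near symmetry; right-handed by
  construction), so rotating the input rotates the sampling with it and
  the areas are bit-identical. The same canonical frame orients the
  Voronoi clipping box. For highly symmetric synthetic point clouds the
  principal axes can be ambiguous; for any realistic protein they are not.
* **Voronoi cell volume**: exact volumes of the Voronoi cells of the Cα
  sites, clipped to the bounding box inflated by 10 Å (computed in the
  canonical frame). Cells are intersections of half-spaces (bisector
  planes + box walls); vertices are enumerated from all constraint
  triples by Cramer's rule, and the polytope volume is assembled from
  facet pyramids. Tests compare against a Monte-Carlo nearest-site
  estimate.
* **Buriedness**: residues with relative SASA ≥ 5% (Tien et al. maximal
  areas) are solvent-accessible sources; everyone else gets the BFS hop
  distance to the nearest source on the Cα ≤ 10 Å contact graph
  (`igraph`), with unreachable residues assigned L. Both thresholds are
  arguments.

In the feature matrix, the three descriptors are z-scored within the
model (a numerical-conditioning choice; raw values remain available),
while lDDT/confidence columns keep their native [0, 1] scale.

## Distance-error features from distograms

A reference distogram assigns each residue pair a distribution over 64
Cβ–Cβ distance bins (first finite edge 2.3125 Å, bin width 0.3125 Å, open
end bins taken with finite pseudo-midpoints half a width beyond the last
edge — the error transform needs finite midpoints). For each distogram
bin the signed error midpoint − d_model accumulates its probability into
one of **nine signed bins** with edges −∞, −4, −2, −1, −0.5, 0.5, 1, 2,
4, ∞ Å. The signed symmetric construction around the four lDDT thresholds
is the unique nine-bin partition of the real line consistent with an
lDDT-style error discretization; because the bins partition the line,
per-pair probability mass is conserved exactly, which the tests assert at
1e-6 and the acceptance script re-measures. Distogram files may carry
probabilities or logits; logits are softmax-normalized. Reference
channels are ordered by `source_id` so feature layout is deterministic.

The contact feature is the average, over the five distograms, of the
probability mass in bins with midpoint ≤ 15 Å; we keep it as a
probability rather than thresholding it (the information is strictly
greater; a threshold option exists). In single-model mode the contact map
is the model's own binary Cβ map with diagonal 1 — the self-pair
contributes only central-bin mass, so no special case is needed in the
initial score.

## Spherical-harmonic edge embedding

Each residue gets a local frame (x = normalized Cα→N; y orthogonal to x
in the N–Cα–C plane, oriented positively along Cα→C; z = x × y). The
direction to every other Cα, expressed in that frame, yields spherical
angles θ (polar, from z) and φ (azimuth, x toward y) — the physics
convention, so the standard harmonic formulas apply verbatim. Real
spherical harmonics of degrees 0–4 (25 channels) are evaluated through
associated Legendre recursions with the Condon–Shortley phase, with the
real forms √2·Re / −√2·Im on top. Two independent checks pin the
implementation: an explicit table oracle (trigonometric polynomial forms
up to l = 4) at 1e-8, and the addition theorem Σ_m Y²_lm = (2l+1)/4π.
Degenerate frames (collinear N–Cα–C within 1e-8) are perturbed by 1e-6 Å
with a warning rather than aborting a batch.

## lDDT flavor

Labels and reference features use Cα-lDDT: inclusion radius 15 Å on the
reference structure, thresholds 0.5/1/2/4 Å, all pairs except self (no
sequence-separation exclusion). Residues whose inclusion set is empty
score 1 (no evidence of error); such residues essentially do not occur in
compact structures. The per-residue values equal a brute-force
double-loop evaluation to 1e-12 in the tests. Since the inclusion set is
defined by the *reference*, the function is deliberately asymmetric in
its arguments.

# Network

## Architecture

Hidden node features (a linear embedding of the node matrix, 32
channels) are tiled to pairs, concatenated with the edge tensor, and
passed through a residual 2D stage — 5 blocks of 32 channels with 3×3
convolutions over the L×L grid, DeepAccNet-style — ending in two
symmetrized heads: 9-class distance-error logits and a 32-channel pair
embedding. The 3×3 kernel is sequence-local by design (it sees
neighboring residue pairs); with `residual_kernel = 1` the stage becomes
pointwise and the whole network is exactly permutation-equivariant under
residue relabeling, which is how the permutation property is tested.

The 9-class probabilities and the contact map produce the initial score
(the contact-weighted mean pass fraction implied by the error bins; we
normalize by the total contact weight so the score is a weighted mean in
[0, 1] — unnormalized it would scale with the contact count). The score
joins the node features for the graph stage.

The graph connects Cα pairs within 15 Å (the Cα choice matches the
coordinates the network updates; a Cβ option exists). Node-level layers
follow the EGNN scheme: messages from (h_i, h_j, ‖x_i − x_j‖², a_ij);
coordinate updates along (x_i − x_j) weighted by a scalar network
φ_x(m_ij), averaged over the |N(i)| neighbors; node updates
h ← φ_h(h, Σ m). The edge attributes a_ij are the 9-class probabilities
concatenated with the pair embedding (41 channels). Edge-level layers
operate on the line graph: undirected edges become nodes carrying a_ij,
their coordinates are the edge midpoints (always recomputed from the
residue coordinates, never updated), connectivity is k = 3 nearest
midpoints with ties broken by the smaller edge index (determinism), and
attributes are midpoint distances; only features are updated. The default
schedule interleaves: node, edge, node, edge, node, node (4 node and 2
edge layers, hidden width 64 — sizes chosen to keep CPU runs comfortable
and in line with common EGNN practice; all configurable).

Heads: per-residue lDDT via sigmoid, and the signed pair error
‖x′_i − x′_j‖ − ‖x_i − x_j‖ over all pairs from the updated coordinates.
The quality head sees, besides the final node features, two invariant
per-residue summaries of what the coordinate pathway did — the residue's
displacement ‖x′_i − x_i‖ and its mean local distance correction — and a
log-odds skip connection from the initial score, so an untrained head
starts at the initial estimate and the graph stage learns a refinement.
This wiring reflects the architecture's intent (the final prediction
comes from updated node features *and* spatial coordinates, refining the
initial score) and, practically, lets the well-conditioned classification
pathway drive quality prediction early in training.

## Equivariance

Coordinates are centered on the model centroid before entering the
network, making translation invariance exact rather than numerical. All
message inputs are invariants; coordinate updates are linear in
difference vectors; therefore predicted lDDT and pair errors are
invariant and updated coordinates equivariant, which the tests verify at
1e-4 over 20 random rigid motions (in practice the error is at machine
precision, ~1e-15, because the descriptors are computed in the canonical
frame).

## Losses and labels

Total loss = CE(initial 9-bin error classification) +
5 · MSE(per-residue lDDT) + 1 · MSE(final pair error), with components
reported separately. Classification labels bin the signed Cβ distance
error of the model against the native (matching the distogram features'
Cβ geometry); the pair-error regression targets d_native − d_model on Cα
(the coordinates the network moves). The regression is *trained* on local
pairs only (model distance within the 15 Å graph cutoff): message passing
on a 15 Å graph carries no information about distant pairs, local errors
are what lDDT itself measures, and with correlated deformations the
all-pairs MSE is dominated by un-learnable long-range terms whose
gradients drown the other heads. The full L×L signed error matrix is
still produced, and the exported `composite_loss()` keeps the plain
full-matrix definition.

## Optimization

Full-scale training (`train_network`, CLI `train`) defaults to the
published regime: SGD, learning rate 1e-6, momentum 0.9, weight decay
5e-5, batch size 1, up to 60 epochs, early stopping after 5 consecutive
non-improving validation epochs, 80/20 train/validation split by target.
Two stabilizers are always on: global gradient-norm clipping (default 10)
and a tanh bound on the coordinate network's scalar output; both leave
the model class unchanged.

The overfit smoke check (`overfit_smoke`) — 200 optimizer steps on one
20-residue target, expecting ≥ 50% loss reduction and pooled
predicted-vs-true per-residue lDDT Pearson ≥ 0.7 over its four decoys —
uses Adam at lr 1e-3. The reason is scale, not fidelity: per-sample
gradient norms of the three loss terms differ by up to two orders of
magnitude across decoys of different quality, and plain SGD at any stable
rate spends the 200-step budget almost entirely on the dominant term.
Adam's per-parameter normalization removes the imbalance; the smoke check
is a gradient-flow and capacity test, not a reproduction of the training
regime. Measured at the default seeds: loss 5.82 → 1.84 (68% reduction),
Pearson 0.91. Weight initialization is uniform fan-in from the
configuration seed, with every coordinate network's final layer zeroed so
that the untrained network is the identity on coordinates.

## Long chains

Chains longer than 850 residues are split into ⌈L/800⌉ near-equal
contiguous segments (each ≤ 800) and per-residue outputs are concatenated
without overlap or smoothing — the stitched prediction restricted to a
segment equals the segment's own prediction exactly. Near-equal sizes
avoid a tiny trailing fragment; overlap was not added because the output
contract is plain concatenation.

# Synthetic data: what it emulates and what it does not

`make_native` builds an ideal α-helix (rise 1.5 Å, 100° turn, radius
2.3 Å, Cα–Cα ≈ 3.8 Å) with N/C placed from the local helix frame at
realistic bond lengths, and ideal tetrahedral Cβ. `make_decoy` adds a
chain-correlated Gaussian displacement field (white noise smoothed along
the sequence with a σ = 4-residue window, rescaled to an exact RMS) applied
rigidly per residue; correlated noise makes true per-residue lDDT vary
smoothly along the chain, so residue-level learning has structure to
find — i.i.d. noise would make every residue statistically identical.
Decoy noise scales default to 0.5/1/2/4 Å, spanning mean lDDT ≈ 0.99 down
to ≈ 0.5. `make_distogram` emulates a well-calibrated predictor: per-pair
Gaussians (spread 1/concentration, slight center jitter) centered on a
structure's own Cβ distances, discretized over the 64 bins by exact
normal-CDF integration. Reference confidences equal the reference's own
true lDDT (a calibrated self-estimate); a bias knob emulates systematic
overconfidence. Attention tensors are symmetric uniform noise — shape and
symmetry only, no signal.

What passing tests on these fixtures shows: the feature algebra, the
invariances, the losses and the optimization path are correct. What they
do not show: performance on real decoys — helices are not folds, the
noise process is not a structure predictor's error process, and the
synthetic attention carries no evolutionary signal. Benchmark-grade
claims would require the community QA datasets and full-scale training,
which are outside this package's scope.

# Numerical choices and degenerate inputs

* PDB fixed-width columns quantize coordinates at 1e-3 Å and b-factors at
  1e-2; round-trip tests use those tolerances. Confidence values > 1 are
  read as a 0–100 pLDDT scale and divided by 100.
* Residues missing any of N/Cα/C are dropped with a warning naming their
  positions; fewer than 2 usable residues is an error. Multi-chain files
  require an explicit chain argument.
* Glycine Cβ is always rebuilt from ideal geometry (bond 1.522 Å,
  tetrahedral angles, L-configuration); for other residues a deposited Cβ
  is preferred, with a `force_virtual_cb` option because some distance
  conventions idealize all Cβ atoms.
* Voronoi vertex enumeration uses a 1e-7 feasibility tolerance and 1e-10
  determinant cutoff; coplanar Cα sets are rejected as degenerate.
* The pair-distance square root is smoothed with ε = 1e-12 so diagonal
  zero distances stay differentiable.
* kNN ties in the line graph break by smaller edge index; all randomness
  flows from explicit seeds, and generators save/restore the caller's RNG
  state.

# Problem sizes used by the test-suite and acceptance script

Unit and property tests run on 10–30-residue fixtures; rigid-motion
properties use 20 random transforms on a 30-residue decoy; the overfit
smoke uses a 20-residue target for 200 steps (~40 s on one CPU core) and
a 40-residue variant in the generator's recovery test (~90 s). These
sizes exercise every code path (multiple segments, both feature modes,
all invariants) while keeping the full suite around three minutes.

# Known limitations

* The residual stage is sequence-local (3×3); strict permutation
  equivariance holds only in the pointwise configuration.
* Voronoi cells are clipped, not unbounded; volumes depend (intendedly)
  on the 10 Å box inflation.
* SASA uses backbone + Cβ pseudo-residues when side chains are absent;
  full-atom areas are computed only from the atoms actually present.
* lDDT here is Cα-based without stereochemistry checks; an all-atom lDDT
  with symmetry corrections is out of scope.
* The SE(3)-transformer variant of the architecture and multi-GPU
  training are not implemented.
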