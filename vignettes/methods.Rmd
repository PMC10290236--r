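---
title: "Scoring docked protein complexes with invariant graph attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring docked protein complexes with invariant graph attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Protein–protein docking produces thousands of candidate poses (decoys) per
chain pair; a scoring function must rank the near-native ones above the
incorrect ones. `graphdock` implements a learned scorer: each chain of a
docked pair is represented as a residue graph with geometry expressed in
per-residue local coordinate frames, a stack of neighbour-attention blocks
embeds each chain, a bi-directional exchange layer passes information across
the interface in both directions, and a pooled head emits a sigmoid
probability that the decoy is near-native. Higher scores mean more
near-native — the opposite orientation from physics-based interface
energies, where lower is better.

## Input representation

A local frame is anchored at every Cα: `b3` is the unit normal of the
N–CA–C plane, `b1` the C–N backbone direction orthogonalized against `b3`,
and `b2 = b3 × b1`. Expressing all vectors in these frames makes every
feature exactly invariant under rigid motions of the complex, which the test
suite checks end to end.

Node features per residue (216 values): a 20-way one-hot amino-acid
identity; for up to 10 heavy side-chain atoms in fixed topology order (CB
outward — 10 covers tryptophan, smaller residues are zero-padded), the
Cα→atom distance under a Gaussian radial basis and the unit direction in
the local frame; and (sin, cos) of φ, ψ, ω, with undefined terminal angles
encoded as the (0, 0) sentinel rather than a learned token.

Edge features connect each residue to its `k = 30` nearest neighbours by
Cα distance (88 values per edge): the RBF-encoded distance, the local-frame
unit direction, the relative-orientation quaternion `q(R_i R_jᵀ)` with its
scalar part canonicalized non-negative, and a one-hot relative sequence
offset clipped to ±32 (65 bins). Inter-chain edges (to the `m = 10` nearest
partner-chain residues of each interface residue) carry the same blocks
minus the sequence offset, which has no meaning across chains.

Numerical choices worth knowing:

* The RBF basis is 16 Gaussians evenly spaced on 0–20 Å with width equal to
  the spacing; this covers contact through mid-range distances and is
  exposed in `feature_config()`.
* Neighbour ordering compares distances at 1 µÅ resolution and breaks ties
  by lower residue index. Idealized fixtures contain exactly tied distances,
  and raw floating-point ordering would let a global rotation permute
  neighbours; the tolerance makes the k-NN graph stable and deterministic.
* Near 180° relative orientations the quaternion scalar part is numerically
  zero and its sign is noise, so the sign canonicalization there falls back
  to the largest-magnitude vector component.
* Residues missing any of N/CA/C are dropped at parse time (the frame needs
  all three); `seq_index` is the gap-free post-filter rank and drives the
  relative-position encoding, while author numbering is kept for reports.
* Interface membership for the exchange layer uses a Cα–Cα cutoff of 10 Å
  (configurable). The 6 Å rule is a separate, stricter criterion used only
  to decide whether two chains interact at all; 10 Å keeps the exchange
  layer populated for perturbed decoys whose contacts have loosened.

## The network

Defaults (`model_config()`): `d_model = 16`, 3 heads, 3 layers,
`d_k = 16`, `d_v = 32`, `d_inner = 16`. Each block applies, per chain,
multi-head attention in which queries come from the node embedding and
keys/values from the edge features with the neighbour's current embedding
concatenated on, scaled by `1/√d_k` and softmax-normalized over the valid
neighbour slots. The original description invokes the standard Transformer
operation without detailing normalization, so each sub-layer here uses the
conventional residual + layer-norm arrangement with a position-wise
feed-forward (ReLU) after the attention — a documented design choice, as is
the masked-mean pooling into a concatenated `[A; B]` vector and two-layer
head.

The exchange layer extracts the interface rows of one chain's embedding,
attends over their inter-chain edges (partner node embeddings concatenated
onto the edge features), and writes the updated rows back in place. The
A-direction runs first; by default the B-direction then reads A's
*already-updated* matrix (`exchange_mode = "sequential"`). A
`"simultaneous"` mode that reads the pre-update snapshot is provided because
the original description does not pin this down. Each direction has its own
weights in every layer. An empty interface makes the exchange an identity,
so chains that do not touch can still be scored.

Training minimizes binary cross-entropy with Adam at learning rate 1e-4
(fine-tuning: 1e-5, warm-started), one complex per step. Validation loss is
checked four times per epoch; training stops after 3 checks without
improvement and returns the best-validation weights. Dropout (default 0.1)
is applied to each sub-layer output before its residual; inference always
runs with dropout off, so scoring is deterministic. All randomness —
initialization, shuffling, dropout — derives from the single config seed,
and the forward/backward passes are plain base-R matrix algebra checked
against central finite differences in the tests.

## Decoy quality and labeling

`fnat` is the fraction of native inter-chain residue contacts (any
heavy-atom pair ≤ 5 Å) recapitulated by the decoy. `interface_rmsd`
superposes the decoy onto the native over the backbone atoms of the native
interface residues (any heavy atom within 10 Å of the partner chain) and
reports the RMSD of those atoms; `ligand_rmsd` superposes on the receptor
backbone only and reports the ligand backbone RMSD. The 5 Å and 10 Å
cutoffs follow the community assessment convention and are configurable,
since the upstream description does not print them. The four-level CAPRI
class is applied from a decision table shipped as reviewable data
(`inst/extdata/capri_criteria.csv`): high requires fnat ≥ 0.5 and (LRMSD ≤ 1
or iRMSD ≤ 1), medium fnat ≥ 0.3 and (LRMSD ≤ 5 or iRMSD ≤ 2), acceptable
fnat ≥ 0.1 and (LRMSD ≤ 10 or iRMSD ≤ 4); the mapping is monotone in every
metric.

Two labeling conventions are supported and flagged per record:
pre-training labels acceptable-or-better as positive and subsamples
negatives (seeded, never upsampling) to equality, keeping the positive
quality mix as generated; fine-tuning labels positive iff iRMSD ≤ 4 Å,
boundary inclusive, with no balancing. The redundancy filter consumes
precomputed sequence-cluster and TM-score tables (running the clustering
and structure-alignment tools is out of scope): an example sharing a
cluster with a holdout member is removed, then any example with maximum
TM-score ≥ 0.4 against a holdout reference (0.40 removed, 0.39 kept).

## Ranking evaluation

ROC AUC uses the midrank formulation (ties count half). Average precision
is the uninterpolated step sum `Σ (R_n − R_{n−1}) P_n` over thresholds at
each distinct score, descending. The hit rate in the top N is
`100 · n_near-native / N` with ties broken deterministically by decoy id —
the rule is explicit because tie handling is a documented source of
discrepancies between published hit counts. The resampled AP comparison
draws the same seeded 10% subsample (without replacement) for both models
1000 times, records the AP difference, and applies a one-sample t test of
the mean difference against zero; the upstream description names both a
one-sample test and Welch's test for this quantity, which conflates two
procedures — the one-sample location test on the paired differences is
implemented, with a Bonferroni factor available for multiple comparisons.
Subsamples without a positive are redrawn and counted.

## Synthetic fixtures

`make_toy_chain()` builds chains on idealized geometry (helix: 1.5 Å rise,
100° twist, giving the canonical ~3.8 Å Cα spacing; strand: extended
zigzag; coil: helix plus small seeded noise) with one pseudo side-chain
atom per non-glycine residue (a bulky variant places three, exercising the
multi-slot padding path). `make_native_complex()` places two chains by
seeded search so they satisfy the interacting-pair rule (≥ 3 Cα contacts at
6 Å) without clashing. Near-native decoys perturb the ligand rigidly by up
to 1.5 Å and 8° — calibrated so they grade acceptable or better — and
incorrect decoys re-place the ligand on a non-clashing shell with every
native contact destroyed (fnat exactly 0, enforced by rejection). Generated
positives and negatives are separable by iRMSD with a ≥ 2 Å margin, which
is what makes the desk-scale learnability check well-posed.

What the fixtures do *not* emulate: real side-chain packing and repacking,
backbone flexibility, the energy-guided sampling of actual docking
protocols, and the hard middle ground of acceptable-but-not-good decoys.
A model that separates these fixtures has demonstrably learned to read the
interface geometry through the exchange layer — incorrect fixtures present
an empty interface, so intra-chain features alone cannot separate the
classes — but no claim about performance on real decoy sets follows.

## Problem sizes and determinism

The shipped tests run the whole stack at deliberately small scale: chains
of 10–25 residues, 200-decoy training studies, 10 epochs — sizes chosen so
the complete suite exercises every code path, including training, in a few
minutes on one CPU. `scripts/acceptance.R` re-runs the same study from a
command-line seed and writes the held-out AUC/AP, top-10 hit rate, loss
trajectory summaries, and the measured invariance deviation as JSON. Every
quantity it reports is recomputed at run time; identical seeds reproduce
byte-identical fixtures, features, initial weights and training histories.

## Known limitations

Only pairwise (two-chain) complexes are embedded; higher-order assemblies
would need multi-chain exchange. PDB-format input only (biounit files are
assumed pre-expanded); mmCIF is out of scope. No structure repair or
protonation. The dropout rate, normalization placement and pooling operator
are design choices where the original description is silent; they are
exposed in the config rather than asserted as canonical.
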