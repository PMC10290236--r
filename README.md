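# graphdock

Scoring function for protein–protein docking decoys, built on an
SE(3)-invariant graph representation of the two docked chains and a
neighbour-attention network with bi-directional interface information
exchange.

## The problem

Docking pipelines generate large sets of candidate poses (*decoys*) for a
receptor–ligand chain pair; the scoring stage must rank near-native poses
above incorrect ones. `graphdock` provides a learned scorer plus the
machinery around it: decoy quality metrics and CAPRI-style grading,
labeling and class-balancing rules for building training sets, redundancy
filtering against holdout targets, ranking evaluation, and a deterministic
synthetic-complex generator so the entire pipeline runs and is tested with
no external data.

## The model

Each chain becomes a residue graph. A local coordinate frame is anchored at
every Cα (built from the N, CA, C atoms), and all geometry is expressed in
those frames, making every feature exactly invariant to rigid motions of
the complex. Nodes carry the one-hot amino-acid identity, RBF-encoded
Cα→side-chain-atom distances with local-frame directions over 10 fixed
atom slots, and the (sin, cos) torus embedding of φ, ψ, ω. Edges connect
each residue to its k = 30 nearest neighbours and carry the RBF-encoded
Cα–Cα distance, local-frame direction, relative-orientation quaternion
q(R<sub>i</sub>R<sub>j</sub>ᵀ), and a clipped one-hot sequence offset.

Stacked blocks (3 layers, d_model = 16, 3 heads, d_k = 16, d_v = 32,
d_inner = 16) update each chain by multi-head attention over its
neighbours, where queries come from the node embedding and keys/values
from edge features concatenated with the neighbour's embedding:

    Attention(Q, K, V) = softmax(QKᵀ / √d_k) V

A bi-directional exchange layer then updates the interface residues of
chain A by attending over edges to the m = 10 nearest residues of chain B
(partner embeddings concatenated onto the edges), and repeats in the other
direction using A's already-updated matrix. Chain embeddings are
mean-pooled, concatenated, and mapped to a sigmoid probability of being
near-native — **higher scores are better**. Training is binary
cross-entropy with Adam at lr 1e-4 (fine-tuning at 1e-5) with early
stopping on validation loss. Forward pass, backpropagation and optimizer
are implemented in base-R matrix algebra and verified against finite
differences and per-residue loop oracles in the test suite.

## Worked example

```r
library(graphdock)

spec   <- fixture_spec(seed = 1)          # synthetic two-chain target
native <- make_native_complex(spec)
native
#> <complex_structure> synthetic-1
#>   chain A : 24 residues
#>   chain B : 18 residues

decoy <- perturb_near_native(native, seed = 2)   # near-native pose
quality_metrics(decoy, native, "A", "B")
#>       irmsd fnat     lrmsd capri_class
#> 1 0.2291767    1 0.5023373        high

bad <- randomize_placement(native, seed = 3)     # incorrect pose
quality_metrics(bad, native, "A", "B")
#>      irmsd fnat    lrmsd capri_class
#> 1 13.10985    0 44.23458   incorrect

params <- init_model(model_config(seed = 1))     # untrained weights
feats  <- featurize_complex(decoy$chains$A, decoy$chains$B)
score_complex(feats$graph_a, feats$graph_b, feats$inter, params,
              metadata = "decoy-002")
#> <score_prediction> p(near-native) = 0.5742 (logit 0.2992) [decoy-002]
```

The quality metrics read as usual: iRMSD is the backbone RMSD of the native
interface residues after optimal superposition, fnat the fraction of native
inter-chain contacts recapitulated, LRMSD the ligand RMSD after superposing
on the receptor; the CAPRI class combines them into
incorrect/acceptable/medium/high. An untrained model scores near 0.5;
`train_model()` fits it (see `vignettes/methods.Rmd` for the full
training and evaluation walk-through). Real structures enter through
`read_structure("file.pdb")` and `select_chain_pair()`.

A command-line wrapper covers the same workflows
(`exec/graphdock fixtures|label|featurize|train|finetune|score|evaluate`).

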