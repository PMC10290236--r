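Package: graphdock
Title: Graph-Attention Scoring of Protein-Protein Docking Decoys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores docked protein-protein complexes with a rotation- and
    translation-invariant graph attention network. Two docked chains are
    converted into per-residue local coordinate frames, radial-basis distance
    encodings, side-chain geometry and backbone torsion features; stacked
    neighbour-attention blocks with a bi-directional interface exchange layer
    pool into a sigmoid probability that the decoy is near-native. Includes
    CAPRI-style decoy quality metrics (fnat, interface RMSD, ligand RMSD),
    labeling and class-balancing rules for building training sets, redundancy
    filtering against holdout targets, ranking metrics (ROC AUC, average
    precision, hit rates), and a deterministic synthetic-complex generator so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
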