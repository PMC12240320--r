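Package: complexdyn
Title: Conformational Dynamics Analysis of Protein Complex Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterizing molecular-dynamics trajectories of
    two-chain protein complexes: multi-model PDB input/output with atom
    selections, Kabsch superposition with pairwise 2D-RMSD matrices,
    threshold-based conformational clustering with representative-structure
    selection, per-residue RMSF profiles with relative-flexibility classes,
    hydrogen-bond and salt-bridge detection with occupancy persistence tiers,
    interface-residue mapping at distance cutoffs, backbone dihedral and
    Ramachandran ensemble comparison, essential-dynamics PCA and dynamic
    cross-correlation matrices, consensus-interface contact classification,
    and a synthetic-trajectory generator with known ground truth for
    validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
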