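Package: ProteinBlocks
Title: Protein Blocks Structural Alphabet Assignment and Local
    Deformability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes protein backbone conformations as sequences over the
    16-letter Protein Blocks (PB) structural alphabet. Each residue is
    assigned the PB prototype whose eight reference dihedral angles
    (psi/phi over a five-residue window) are nearest in the RMSDA angular
    metric, with a dummy block 'Z' where the window is incomplete.
    Assignments over conformational ensembles (multi-model PDB files or
    molecular-dynamics trajectories) are aggregated into per-residue count
    matrices, from which the package computes PB frequency maps, logo
    data, and the Neq entropy profile (the equivalent number of PBs
    sampled per residue, a measure of local backbone deformability).
    Includes a synthetic-backbone generator for prescribed phi/psi angles
    and three chainable command-line programs (PBassign, PBcount,
    PBstat).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
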