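Package: pldiff
Title: Equivariant Diffusion Generation of Protein-Ligand Complex Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A variance-preserving diffusion generative model over the joint 3D
    coordinates of protein C-alpha atoms and ligand heavy atoms, conditioned on
    the protein sequence and the ligand molecular graph. Provides the noise
    schedule and zero-centroid subspace Gaussian machinery, an SE(3)-equivariant
    noise-prediction network built from pair-biased attention blocks, the
    variational diffusion training objective with Adam, learning-rate warm-up
    and parameter averaging, an ancestral sampler that generates structure
    ensembles, and ensemble evaluation via TM-score and ligand RMSD after
    protein superposition. Includes a deterministic toy-complex generator so
    the full train/sample/evaluate pipeline runs from synthetic fixtures, plus
    readers and writers for FASTA, SDF/MOL, multi-model PDB, a JSON ligand
    dialect, and YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    Biostrings,
    ChemmineR,
    igraph
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
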