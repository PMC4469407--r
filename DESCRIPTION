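Package: poseatlas
Title: Ensemble Analysis of Peptide-GPCR Docking Poses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rigid-body docking pose ensembles of peptide
    ligands in G protein-coupled receptor (GPCR) binding cavities. Reads
    multi-model PDB pose ensembles in a shared receptor frame, resolves
    Ballesteros-Weinstein residue annotations, applies interface and membrane
    admissibility filters, computes all-pairs alpha-carbon RMSD matrices
    without superposition, clusters poses with the greedy neighbour-count
    (Daura) algorithm, ranks clusters by median refinement score, embeds pose
    landscapes in two dimensions by metric multidimensional scaling (SMACOF
    stress majorization), measures binding depth and rotational azimuth in a
    membrane frame anchored on a three-residue zero-plane, computes
    Shrake-Rupley solvent-accessible surface areas, maps receptor-ligand
    contacts at a distance cutoff, and classifies poses into alternative
    rotational binding modes. Ships a deterministic synthetic pose-ensemble
    generator with planted clusters, rotational modes, and membrane decoys so
    the whole pipeline is testable without docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grid,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
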