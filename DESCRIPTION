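Package: gpcrmd
Title: Trajectory Analysis of GPCR-Radioligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of conformational ensembles of receptor-ligand
    complexes, aimed at judging chelator-peptide radiopharmaceuticals bound
    to class-A G-protein-coupled receptors such as the somatostatin
    receptor 2. Provides per-frame activation-state classification from
    geometric markers, a pairwise nonbonded evaluator giving the
    ligand-receptor Coulomb and Lennard-Jones interaction energy and its
    per-residue decomposition, root-mean-square-fluctuation statistics for
    loop flexibility after Kabsch superposition, a contact census with
    side-chain-class typing, center-of-mass penetration metrics, and a
    synthetic two-state ensemble generator so that every stage is
    verifiable without running molecular dynamics. Reads multi-model PDB
    trajectories with a JSON topology sidecar carrying charges,
    Lennard-Jones parameters and masses; results are tidy tibbles with
    tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
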