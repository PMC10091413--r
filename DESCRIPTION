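Package: pocketforge
Title: Ligand- and Mutagenesis-Guided Refinement of GPCR Binding-Site Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for refining the orthosteric binding site of
    low-homology G-protein-coupled receptor (GPCR) models with ligand and
    mutagenesis information.  Provides ensemble model evaluation by
    screening enrichment (tie-aware ROC/AUC and a top-fraction enrichment
    factor with its analytic maximum), geometric pose filtering against
    mutagenesis-identified residue pairs, binding-site pose clustering
    with Kelley-penalty dendrogram level selection, orchestration of
    iterative flexible-residue docking rounds behind a pluggable engine
    interface, and voxel volume-overlap shape-space analysis of backbone
    loops.  Includes synthetic generators (toy receptors, pose clouds,
    calibrated score tables, loop families) and a deterministic mock
    docking engine so the full protocol can be exercised without any
    commercial docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
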