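Package: commscore
Title: Directional Cell-to-Cell Communication Scoring from Transcriptomes
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers directional cell-to-cell communication from bulk or
    single-cell transcriptomic profiles. Combines a curated multi-subunit
    ligand-receptor interaction database with per-gene max-scaled expression
    to compute per-interaction and global communication scores between a
    central cell population and partner cell types, in both outward
    (central ligands to partner receptors) and inward directions.
    Provides score normalization to a reference condition, 1-10 rescaling
    for display, replicate-wise Wilcoxon comparison of score distributions
    with Benjamini-Hochberg adjustment, single-cell cluster averaging and
    subsampling robustness analysis, four visualization modes (network,
    stacked family barplot, balloon plot, p-value heatmap), a seeded
    synthetic-data generator with closed-form expected scores, and a
    command-line interface with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
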