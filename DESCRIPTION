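Package: mechbridge
Title: Mechanical Bridging Scores from Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds distance-fluctuation coupling networks from ensembles of
    C-alpha protein conformers, scores every residue by the spectral softening
    that the virtual deletion of its non-bonded couplings causes in the
    normalized graph Laplacian (the mechanical bridging score), aggregates
    profiles across homologous receptors through generic residue numbering,
    validates score rankings against key-site lists with ROC curves, and
    provides a simplified quasi-rigid domain decomposition of the same
    network. Includes a synthetic generator of hinged rigid-body C-alpha
    ensembles for end-to-end testing without external structure downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
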