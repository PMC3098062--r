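Package: pocketshapes
Title: Rotameric Ensembles and Volumetric Shape Fingerprints of Protein
    Ligand-Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the conformational flexibility of a protein
    ligand-binding site on a fixed backbone. Given a template structure
    (and optionally superposable ligand-bound homolog structures), the
    package selects the binding-site residues, exhaustively enumerates
    sterically allowed combinations of side-chain rotamers, represents
    each conformer's pocket shape as a bit string over a 3D lattice,
    prunes and merges near-identical shapes, clusters the shapes by
    Tanimoto dissimilarity with medoid representatives, scores
    ligand-pocket shape incompatibility, and ranks the residues that
    dominate pocket-shape variation. Includes a deterministic synthetic
    toy-system generator so the whole pipeline is testable without
    external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
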