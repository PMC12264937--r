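Package: psrt
Title: Persistent Stanley-Reisner Theory for Molecular Featurization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for commutative-algebra analysis of 3D point clouds and
    molecular structures via persistent Stanley-Reisner theory: abstract
    simplicial complexes with their Stanley-Reisner ideals, f-/h-vectors and
    Hilbert functions; Vietoris-Rips and bipartite filtrations; facet
    persistence barcodes and facet persistence Betti numbers; persistent
    graded Betti numbers through Hochster's formula; and persistent f-/h-
    vectors. On top of the algebraic core, the package provides
    element-specific and category-specific featurization of
    (metallo)protein-ligand binding pockets and a gradient-boosted
    regression head for binding-affinity modelling, together with
    deterministic synthetic fixtures (a parametric C60 fullerene and
    random binding pockets) and a small command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
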