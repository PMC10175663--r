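Package: pepsim
Title: Peptide-HLA Similarity Scoring for T-Cell Cross-Reactivity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the pairwise similarity of peptide-HLA class I complexes by
    fusing peptide sequence similarity (BLOSUM62 sums, entropy-weighted
    substitution-matrix scores, Hamming distance) with a six-dimensional
    structural and biochemical distance computed by iterative-closest-point
    registration of biochemically annotated molecular surface patches.
    Co-clustered complexes are predicted to be cross-reactive for the same
    T-cell clone. Includes synthetic peptide-HLA fixture generators, surface
    meshing and annotation (electrostatics, hydrophobicity, hydrogen-bond
    potential), agglomerative clustering, leave-one-out k-nearest-neighbour
    validation, target ranking and non-metric multidimensional scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    ape,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
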