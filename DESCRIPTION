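Package: enqar
Title: Equivariant Graph Networks for Protein Model Quality Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-residue and per-model accuracy (lDDT) of predicted
    protein tertiary structures with an E(n)-equivariant graph neural
    network. Implements the full feature pipeline (solvent-accessible
    surface area, Voronoi cell volumes, buriedness, real spherical-harmonic
    edge embeddings in local backbone frames, and distogram-derived
    distance-error probabilities), a two-level equivariant network built on
    a residual 2D stage, composite-loss training with SGD, long-chain
    cropping, and a synthetic fixture generator so the whole system runs
    self-contained without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
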