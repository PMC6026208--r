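Package: ommscreen
Title: Quantitative Screening of Ommatidial Disorder, Genetic Interactions,
    and Network Connectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative genetic-modifier screens built around the
    Drosophila compound eye. Provides an image-based phenotypic score of
    ommatidial lattice disorder (blob detection plus local six-neighbour
    vector geometry), a two-way ANOVA classifier of two-hit epistasis
    (suppressor, enhancer, additive, full rescue), parametric gene-set
    enrichment (PAGE Z-scores) with Benjamini-Hochberg correction, a
    permutation test for cross-model overlap of differentially expressed
    genes, and shortest-path connector-gene analysis on weighted functional
    networks with Fisher enrichment and random-seed controls. A seeded
    synthetic-data module generates eye images, replicate score tables,
    multi-model expression studies, and random networks with known ground
    truth, so every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    igraph,
    car,
    yaml,
    jsonlite,
    png,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
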