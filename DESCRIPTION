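Package: spinalatlas
Title: Marker-Driven Cell-Type Classification for the Developing Spinal Cord
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for marker-driven analysis of single-cell RNA-seq data
    from the developing spinal cord and dorsal root ganglia: droplet-level
    quality control, gene-module scoring with expression-matched control
    genes, two-step knowledge-matrix classification of cells into broad
    tissues and dorsoventral progenitor/neuronal subtypes (plus peripheral
    sensory lineages), cross-species per-type correlation over one-to-one
    orthologs, in vivo/in vitro staging correlation, composition and
    neurogenesis-rate dynamics across developmental stages, and gating and
    characterisation of OLIG2/NKX2-2 double-positive progenitors.  Includes
    a ground-truthed negative-binomial count simulator that emulates the
    statistical structure the downstream analysis assumes, and a
    command-line pipeline for reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
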