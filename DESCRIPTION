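Package: miRConverge
Title: Convergence Analysis of Heterogeneous Circulating miRNA Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for testing whether heterogeneous sets of differentially
    expressed circulating microRNAs converge on a common, functionally
    interconnected cluster of target genes. Implements per-gene
    miRNA-targeting frequency scores from miRNA-target interaction tables,
    a permutation null for target-set convergence and protein-protein
    interaction interconnectivity, curation and trimming of directed
    signed gene-gene networks, Katz-centrality-based combined gene scores,
    and a path-attenuation influence score ranking individual miRNAs by
    their contribution to the downstream phenotype. Includes seeded
    synthetic-data generators with a planted convergent gene cluster so
    the whole pipeline can be exercised and calibrated without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
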