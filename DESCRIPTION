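Package: tscc
Title: Two-Stage Combinatorial Clustering of Docked Ligand Poses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of structure-based virtual screening results by
    two-stage combinatorial clustering. Docked ligand poses are first clustered
    by atomic-level protein-ligand interaction profiles computed with a
    piecewise-linear potential (hydrogen-bond and steric classes) plus a
    Coulomb term, using correlation distance and UPGMA. Compounds within each
    interaction cluster are then clustered by binary Carhart-style atom-pair
    topological descriptors under Tanimoto distance, and the lowest-energy
    member of every structural sub-cluster is selected as its representative.
    Includes reference-threshold learning by maximum discrimination between
    intra- and inter-class pair distances, intra/inter t-test validation, and
    a deterministic synthetic-data generator (toy receptors, multi-mode pose
    sets, scaffold families) for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
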