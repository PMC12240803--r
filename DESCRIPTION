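Package: tardis
Title: Terrains and Routes Directed in Space-Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents time-ordered palaeogeographic elevation rasters as a
    weighted spatiotemporal lattice graph and estimates climate-niche
    constrained least-cost dispersal paths between phylogenetic
    ancestor-descendant locations. Computes BIOCLIM bioclimatic variables
    from monthly climatologies, builds a PCA climate space from tip
    conditions, reweights landscape edges by squared residual distance to
    ancestor-descendant niche trajectories, measures dispersal rates along
    least-cost paths, reconstructs ancestral climatic tolerances by
    Brownian-motion generalized least squares, and quantifies climate-space
    disparity through time with binned bootstrap confidence intervals.
    Includes a seeded synthetic-fixture generator (terrain, climatology,
    phylogeny, anchors) so the full pipeline runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
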