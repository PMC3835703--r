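Package: netscene3d
Title: Three-Dimensional Network Scenes with Multilevel Force-Directed
    Layout, Time-Course Animation and Assembly-Graph Bubble Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds, lays out and animates attributed biological networks in
    three dimensions. Provides a 3D Fruchterman-Reingold spring embedder and a
    multilevel coarsen/prolong/refine scheme for large graphs; visual-attribute
    mapping of time-course values onto node sizes, edge thicknesses and
    heat-map colours; motion networks that replay condition series as
    insert/delete events on a shared union layout; scene synchronization via
    ordered mutation-event streams; readers and writers for SIF, Cytoscape
    attribute files, tab-separated time-course tables, Velvet LastGraph,
    GraphML and a documented scene JSON; conversion of Velvet assembly graphs
    to networks with detection of bubbles (reconvergent path pairs); and
    seeded synthetic fixtures for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    xml2,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
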