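Package: rnaspring
Title: Force-Directed Layout of RNA Secondary Structures on Compressed Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Draws pseudoknot-free RNA secondary structures with a
    physics-based layout engine. Structures read from dot-bracket, CT or
    BPSEQ files are decomposed into loops and base pairs and mapped onto a
    compressed graph (one vertex per loop and per stem base pair). Vertex
    positions evolve under Newtonian attraction and loop-loop repulsion
    forces, integrated either with the explicit Forward Euler scheme or the
    implicit Backward Euler scheme solved per vertex by Newton's method with
    an analytic 2x2 Jacobian, which remains stable at far larger time-steps.
    Converged vertex positions are expanded to per-nucleotide coordinates
    honouring the standard drawing conventions (circular loops, equidistant
    base pairs) and rendered to SVG. A generator of random valid structures
    supports testing without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    xml2,
    igraph,
    optparse
Config/testthat/edition: 3
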