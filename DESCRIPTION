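Package: wirefold
Title: Design of DNA and RNA Wireframe Nanostructures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns a 3D polygon-mesh wireframe (Wavefront OBJ) into a fully
    specified DNA or RNA nanostructure. Implements five strand-routing
    methods (A-trail Eulerian scaffold routing, spanning-tree scaffold
    routing for DNA, antiparallel double cycle cover, spanning-tree RNA
    origami with kissing loops, and Xuong-tree RNA routing that minimises
    the kissing-loop count), a rigid-cylinder double-helix model with
    optional spring relaxation, a nucleotide-level 3D model with linker
    placement and strand nicking, primary-sequence design (scaffold
    complementation and Focused Metropolis Search), and export to the
    oxDNA, UNF and CSV formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
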