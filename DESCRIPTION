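Package: godagr
Title: Graph-Based Exploration of Gene Ontology DAGs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the directed acyclic graph (DAG) structure of
    Gene Ontology namespaces. Reads OBO 1.2 ontologies and GAF 2.x annotation
    files, assigns hierarchy levels by the longest-path rule, categorises terms
    as leaf, regular or jump nodes, collapses a GO-DAG into a small reduced DAG
    suitable for visualisation, ranks term lists by their vertical position in
    the DAG, and prioritises term lists by iterative elimination along shortest
    paths to the root. Includes a seeded synthetic-DAG generator for testing and
    DOT/GraphML export, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, igraph, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
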