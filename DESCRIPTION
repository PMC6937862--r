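Package: pathdom
Title: Dominator-Tree Analysis of Signalling Pathways with Mutation Overlay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a signalling pathway as a rooted directed graph, computes
    its dominator tree from a chosen signal entry point with the
    Lengauer-Tarjan algorithm, and overlays per-gene somatic mutation
    frequencies and oncogene/tumour-suppressor annotations so that
    positionally dominating mutated genes can be identified. Reads KEGG
    pathways in KGML (XML) format and mutation tables in TSV/MAF-compatible
    form, and exports annotated graphs and trees as GraphML, Graphviz DOT,
    node-link JSON and plain-text reports. Includes seed-deterministic
    generators for random rooted digraphs, KGML files and synthetic mutation
    tables used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
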