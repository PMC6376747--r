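Package: codeviews
Title: Hierarchical Rollup, Filtering, and Comparison of Coded Health Data Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytics for aggregated health data sets coded with hierarchical
    terminologies (ICD-9-CM, ICD-10-CM, MeSH, or generic parent-child edge
    lists). Computes node counts (NC, raw usage frequency), class counts (CC,
    the rollup of NC over a node's distinct descendants in the terminology
    DAG), and child/parent CC ratios; filters by threshold, top-k, or top
    percent; systematically compares two data sets node by node with
    proportion differences and optional chi-square tests; and extracts
    ancestor-closed summary-view subgraphs with red-to-green color scaling,
    exported as Graphviz DOT, GraphML, and CSV. Includes a seeded synthetic
    generator of random hierarchies and Zipf-distributed code frequencies,
    dataset validation against minimum-size acceptability rules, and a
    command-line workflow (validate, preview, analyze, compare, generate).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
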