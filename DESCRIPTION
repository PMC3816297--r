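Package: provflow
Title: Provenance Graphs for Bioinformatics Workflow Executions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, validate and persist PROV-DM-style provenance graphs for
    genome-project workflow executions. Accounts (one graph per workflow
    execution) hold typed nodes (agents, activities, entities, collections)
    and typed relations (used, wasGeneratedBy, wasAssociatedWith,
    wasDerivedFrom, memberOf) as tibbles; wasDerivedFrom edges are maintained
    automatically from used/wasGeneratedBy pairs. Structural, temporal and
    functional restrictions are checked and account- and project-level
    validity is inferred on the three axes. Accounts round-trip through a
    versioned XML dialect with a per-project registry, payload files are
    linked at a second granularity level, and group-filtered views are
    rendered to GraphViz DOT. Ships a builder for the Bacillus cereus
    alpha-amylase case-study graph and a seeded generator of valid and
    deliberately invalid accounts for property testing, plus a scriptable
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
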