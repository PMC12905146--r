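Package: seacdm
Title: Study-Experiment-Assay Common Data Model Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An ontology-aware data-integration engine built on the
    Study-Experiment-Assay common data model (SEA CDM) for heterogeneous
    biomedical study metadata. Provides the 13-class schema with validation
    and SQL DDL emission, per-class CSV templates, an embedded relational
    store with the canonical sample-summary query, ontology term hierarchies
    with transitive subClassOf traversal, ETL connectors for VIGET-,
    ImmPort-, and CELLxGENE-shaped sources, a paired-sample query engine
    with the stimulated-gene fold-change statistic, a property-graph export
    for graph databases, and a seeded synthetic-study generator with
    planted differential genes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    rhdf5,
    optparse,
    withr
Config/testthat/edition: 3
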