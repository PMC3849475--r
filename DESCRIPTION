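Package: illicitnet
Title: Bipartite Drug-Target Network Analysis of Illicit Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bipartite drug-target networks from DrugBank-dialect XML
    records, recruits an illicit-extended network of drugs sharing targets
    with illicit drugs, flags hub and bridge nodes from degree and
    betweenness distributions, and runs the associated enrichment
    statistics: two-sided Fisher exact tests over ATC second-sublevel
    therapeutic categories, comparative GO Slim and two-stage KEGG-style
    pathway enrichment of target-gene sets, hypergeometric candidate-gene
    overlap tests, and Wilcoxon degree comparisons. Includes a seeded
    synthetic-data generator with planted hubs, bridge genes and category
    enrichment so the whole pipeline is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
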