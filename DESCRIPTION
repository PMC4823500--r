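Package: pharmnet
Title: Network Pharmacology of Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds and analyses the interaction networks used in network
    pharmacology studies of multi-herb formulas: compound-target bipartite
    networks, herb-target-disease networks, and first-neighbor PPI expansion
    networks. Scores nodes by degree, normalized betweenness, and
    component-corrected closeness; selects major (hub) nodes by joint
    above-mean thresholds; nominates potential drug targets by intersection
    with compound targets; and scores functional-term enrichment with fold
    enrichment and hypergeometric (or EASE) p-values. Includes a seeded
    synthetic-study generator with planted hubs and planted enriched terms so
    the full pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
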