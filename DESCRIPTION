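Package: ncaxis
Title: Seed-Anchored mRNA-miRNA-lncRNA Interaction Networks with GO
    Over-Representation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds filtered tripartite mRNA-miRNA-lncRNA interaction
    networks from curated gene or protein biomarker lists and an
    NPInter-style table of experimentally validated ncRNA interactions.
    Provides occurrence-threshold filtering and single-interactor pruning,
    detection of lncRNA-governed miRNA blocks, a reverse query for genes
    governed through block-linked lncRNAs, propagation of binary
    expression-state hypotheses under competing-endogenous-RNA (sponge)
    logic, expansion of retained genes with first-degree BioGRID
    interactors, and Gene Ontology over-representation analysis
    (right-tailed hypergeometric test with Holm step-down correction)
    from local OBO and GAF files. A deterministic synthetic fixture
    generator with planted network and enrichment structure supports
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
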