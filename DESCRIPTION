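Package: imepp
Title: Essential Protein Identification from Weighted Protein Interaction
    Networks by Influence Maximization
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks candidate essential proteins in a protein-protein
    interaction network. Edges are weighted by the product of gene
    co-expression (Pearson correlation) and Wang-style Gene Ontology
    semantic similarity; each protein receives an influence score that
    blends its normalized weighted degree with a normalized orthologous
    conservation score; and k candidates are selected greedily under the
    independent cascade model using an influence-discount update.
    Includes degree-discount and degree-centrality baselines, a
    synthetic-data generator that emits complete input bundles (PPI edge
    list, expression matrix, GO ontology and annotations, orthology
    table, gold essential list), top-k evaluation against a gold list,
    lambda sweeps, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
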