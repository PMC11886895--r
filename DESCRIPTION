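Package: cernarisk
Title: Competing Endogenous RNA Risk Networks and Endothelial circRNA
    Circuits for Coronary Artery Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds competing endogenous RNA (ceRNA) networks from scored
    circRNA-miRNA and miRNA-mRNA interaction tables, maps GWAS variants to
    nearby noncoding and coding features by a closest-plus-window proximity
    rule, performs two-group differential expression with fold-change and
    adjusted-p thresholds, extracts a disease-risk ceRNA subnetwork,
    characterizes its topology (degree, betweenness) against the background
    network, runs hypergeometric gene-set enrichment, and prioritizes
    endothelial-cell-specific circRNA regulatory circuits linking variants
    to circRNA-miRNA-gene-program chains. Includes a seeded synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
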