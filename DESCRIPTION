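Package: coexnet
Title: Context-Specific Gene Coexpression Networks Across Many Expression Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines context-specific coexpression of focal genes (for example
    nutrient transporter families) across a collection of independently
    normalized expression datasets. Implements per-dataset one-way ANOVA with
    Benjamini-Hochberg FDR to flag differentially expressed genes,
    dataset-averaged and tissue-stratified Pearson coexpression weights,
    permutation-tested transporter-to-pathway coexpression scores against
    random same-size gene sets, rule-based assembly of top-k gene networks and
    tissue-specific gene-pathway networks, and hypergeometric
    over-representation analysis of network members. A synthetic-data
    generator with planted differential expression and planted correlated
    partners provides a ground-truth test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
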