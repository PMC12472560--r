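Package: myconet
Title: Fungal Co-Occurrence Network Stability from ASV Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the stability of soil fungal communities
    from ITS amplicon sequence variant (ASV) count tables. Builds
    per-treatment co-occurrence networks (Spearman rank correlation with
    Bonferroni gating), summarises network topology, computes null-model
    community cohesion and the negative-to-positive cohesion stability
    ratio, simulates network robustness under random and degree-targeted
    node removal, assigns fungal functional guilds from a lookup reference,
    and correlates guild relative abundance with network stability.
    Includes rarefaction, alpha diversity (Chao1, Shannon), Bray-Curtis
    ordination and PERMANOVA, and a synthetic-data generator that plants
    co-abundance modules and guild composition shifts for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    vegan,
    SummarizedExperiment,
    S4Vectors,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
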