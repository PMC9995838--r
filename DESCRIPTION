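Package: cecalink
Title: Linking Cecal Microbiota Co-Abundance Networks to Growth Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for relating gut (cecal) microbial communities to a
    quantitative host phenotype such as market weight. Implements feature-table
    filtering, rarefaction and taxonomic aggregation; alpha diversity (Shannon,
    Simpson, Chao1, ACE, Faith's PD), unweighted UniFrac, principal coordinate
    analysis and PERMANOVA; SparCC compositional correlation inference with
    bootstrap significance and co-abundance-group (CAG) construction with
    Ward clustering, per-CAG validation and maximal-clique-centrality hub
    ranking; a two-part (presence + conditional log-abundance) association
    model with unweighted-Z meta-analysis, Benjamini-Hochberg correction and
    cross-validated estimation of phenotypic variance explained by the
    microbiota; LEfSe-style effect sizes and random-forest biomarker ranking;
    WGCNA-style metabolite module detection and taxon/metabolite/cytokine
    integration statistics. Ships a synthetic-cohort generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    biomformat,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    pROC,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
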