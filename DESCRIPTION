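Package: micromet
Title: Microbe-Metabolite Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of paired gut microbiome and fecal
    metabolome profiles across experimental groups. Provides exact
    Mann-Whitney differential abundance with fold-change and volcano
    statistics, Shannon and Bray-Curtis diversity, PCA of metabolite
    profiles, compositionally aware SparCC microbe-microbe correlation,
    Spearman metabolite-metabolite and cross-modal correlation layers,
    per-group signed heterogeneous co-occurrence networks with
    triad-ablation (ATria) centrality ranking, KEGG-supported edge
    annotation, network-specific metabolite identification, and a
    synthetic data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    xml2,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
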