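Package: cepinet
Title: Network Entropy and Signed-Motif Analysis of Co-Expressed Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds co-expressed protein interaction networks (CePINs) by
    mapping per-group Pearson correlations of gene expression onto a
    protein-interaction scaffold, then quantifies cellular network
    heterogeneity with normalized local Shannon entropy and structural-balance
    triangle motif censuses. Provides expressed-gene filtering, significance
    filtering of co-expression edges, Wilcoxon rank-sum group contrasts
    (tumor versus normal, stages, smoking status, drug response), a modular
    latent-factor expression simulator for end-to-end validation, and
    tidyverse-style tabular results with tidy()/glance()/autoplot() methods.
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
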