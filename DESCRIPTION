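Package: pathomix
Title: Pathway-Informed Criss-Cross Attention for Multi-Omics Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates multi-modal omics data (gene-, fragment- and
    nucleotide-level features) for sample classification using compacted
    gene embeddings, a pathway-based sparse neural network, and a
    criss-cross attention encoder whose pathway-axis attention is biased
    by a pathway crosstalk network. Includes pathway curation and
    filtering from GMT gene sets, crosstalk network construction via
    enrichment tests, a reverse-mode automatic-differentiation engine for
    end-to-end training, repeated stratified cross-validation with
    macro-F1/AUC/sensitivity-at-fixed-specificity metrics, Shapley-value
    interpretation of pathways, genes and modalities, crosstalk
    sub-network scoring, and a synthetic multi-omics data generator with
    planted pathway-level signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    yaml,
    jsonlite,
    generics,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
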