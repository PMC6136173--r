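Package: viromescope
Title: Quantitative Analysis of Lung DNA Viromes from Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reads-to-ecology pipeline for quantitative DNA virome analysis
    of low-biomass respiratory samples. Simulates shotgun metagenomes with
    host contamination from a designed viral community, performs quality
    trimming, exact-duplicate removal, host decontamination and seed-and-extend
    read mapping, calls viral populations present when reads at >= 95 percent
    identity cover a consecutive 200 bp stretch of a genome, quantifies
    abundance as median coverage normalised to decontaminated read counts,
    aggregates phages by host taxonomy, and compares two subject groups with
    alpha-diversity statistics, Bray-Curtis ordination, permutation factor and
    vector fitting, Mantel tests, a Metastats-style differential-abundance
    test, and compositional association networks via centered log-ratio
    transformation and Meinshausen-Buhlmann neighborhood selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    IRanges,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
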