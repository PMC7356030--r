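Package: beemine
Title: Text-Mining Trends in the Honey Bee Research Literature
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for uncovering research trends in the
    Apis mellifera literature from bibliographic exports. Normalizes
    author-assigned keywords by manual synonym mapping and Porter
    stemming, fits exponential publication-growth curves with doubling
    times, Ward-clusters publication years by keyword frequency profiles
    with bootstrap stability and marginal-sum enrichment scores, builds
    keyword co-occurrence networks under an independence null
    (observed greater than expected edge criterion) with bootstrapped
    transitivity confidence intervals, fits latent Dirichlet allocation
    topic models selected by c_v coherence, and compares topic-word
    networks against keyword networks with exact and substring matching.
    Ships a synthetic corpus generator with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    ape,
    jsonlite,
    readr,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
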