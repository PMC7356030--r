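#' Reproduce headline statistics from a full bibliographic export
#'
#' Given a full-scale Scopus export (and optionally its curated synonym
#' table), re-runs the parts of the pipeline behind the analysis's
#' headline numbers: total and per-period record counts
#' after the five-per-year inclusion threshold, and the global
#' transitivity of the per-period top-49 keyword networks under the
#' O > E edge criterion.
#'
#' @param corpus_csv path to the export in the Scopus CSV dialect.
#' @param synonym_tsv optional path to a variant-to-canonical synonym
#'   table (TSV).
#' @param boundary_year period boundary (default 2006).
#' @param min_per_year inclusion threshold (default 5).
#' @param top_k per-period keyword list size before removing the
#'   search term (default 50).
#' @param exclude keywords removed after ranking (default the stemmed
#'   search term).
#' @return list: `n_total`, `n_pre`, `n_post`, `transitivity_pre`,
#'   `transitivity_post`.
#' @export
verify_deposit_checks <- function(corpus_csv, synonym_tsv = NULL,
                                  boundary_year = 2006L, min_per_year = 5L,
                                  top_k = 50L, exclude = "api mellifera") {
  corpus <- read_publications(corpus_csv)
  corpus <- filter_years_by_min_count(corpus, min_per_year)
  map <- if (is.null(synonym_tsv)) synonym_map() else read_synonym_map(synonym_tsv)
  norm <- normalize_corpus(corpus, map)
  periods <- split_by_period(norm, boundary_year)
  trans <- vapply(periods, function(p) {
    kws <- top_keywords(p, k = top_k, exclude = exclude)
    global_transitivity(build_network(compute_cooccurrence(p, kws)))
  }, numeric(1))
  list(
    n_total = n_publications(norm),
    n_pre = n_publications(periods$pre),
    n_post = n_publications(periods$post),
    transitivity_pre = unname(trans["pre"]),
    transitivity_post = unname(trans["post"])
  )
}
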