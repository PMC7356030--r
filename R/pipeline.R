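#' End-to-end pipeline configuration
#'
#' Bundles every tunable of the full analysis. The defaults reproduce
#' the study settings of the emulated workflow: a minimum of five
#' publications per retained year, a period boundary at 2006, the top
#' 50 keywords per period with the stemmed search term excluded
#' (leaving 49), 1000 bootstrap iterations, an LDA grid of
#' 20/50/70/90/110/140 topics with 20 chosen, ten top words per topic
#' summary and five per topic network.
#'
#' @param corpus_csv,synonym_tsv input file paths; alternatively pass
#'   `synth` to generate the corpus in-memory.
#' @param synth optional [synth_config()]; used when `corpus_csv` is
#'   `NULL`.
#' @param boundary_year first year of the later period (default 2006).
#' @param min_per_year minimum publications per retained year
#'   (default 5).
#' @param top_k top keywords per period before exclusion (default 50).
#' @param exclude keywords removed from the ranked lists (default: the
#'   stemmed search term "api mellifera").
#' @param n_clusters clusters reported for stability/enrichment
#'   (default 6, roughly one per decade).
#' @param enrich_top_n enriched keywords reported per cluster
#'   (default 3).
#' @param n_boot bootstrap iterations for cluster stability and
#'   transitivity CIs (default 1000).
#' @param ci_level transitivity CI coverage (default 0.95).
#' @param k_grid LDA topic-count grid (default
#'   `c(20, 50, 70, 90, 110, 140)`).
#' @param chosen_k LDA model used downstream; default 20. Set to `NULL`
#'   to take the coherence argmax.
#' @param lda_iterations Gibbs sweeps per model (default 200).
#' @param summary_top_n top words per topic summary (default 10).
#' @param network_top_n top words per topic entering the topic network
#'   (default 5).
#' @param seed global seed; each random stage consumes
#'   `seed + stage offset` so stages can be rerun in isolation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus_csv = NULL, synonym_tsv = NULL,
                            synth = NULL,
                            boundary_year = 2006L,
                            min_per_year = 5L,
                            top_k = 50L,
                            exclude = "api mellifera",
                            n_clusters = 6L,
                            enrich_top_n = 3L,
                            n_boot = 1000L,
                            ci_level = 0.95,
                            k_grid = c(20L, 50L, 70L, 90L, 110L, 140L),
                            chosen_k = 20L,
                            lda_iterations = 200L,
                            summary_top_n = 10L,
                            network_top_n = 5L,
                            seed = 1L) {
  if (is.null(corpus_csv) && is.null(synth)) {
    stop("provide either corpus_csv or a synth config")
  }
  structure(
    list(
      corpus_csv = corpus_csv, synonym_tsv = synonym_tsv, synth = synth,
      boundary_year = as.integer(boundary_year),
      min_per_year = as.integer(min_per_year),
      top_k = as.integer(top_k), exclude = exclude,
      n_clusters = as.integer(n_clusters),
      enrich_top_n = as.integer(enrich_top_n),
      n_boot = as.integer(n_boot), ci_level = ci_level,
      k_grid = as.integer(k_grid), chosen_k = chosen_k,
      lda_iterations = as.integer(lda_iterations),
      summary_top_n = as.integer(summary_top_n),
      network_top_n = as.integer(network_top_n),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# stage seed fan-out: a fixed offset per random stage, so reruns of a
# single stage reproduce the full-run stream
stage_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

#' Run the full literature-trend analysis
#'
#' Sequence: ingest -> year threshold filter -> keyword normalization
#' -> growth trends -> period split -> per-period top keywords ->
#' union keyword-year matrix -> Ward year clustering with bootstrap
#' stability and enrichment -> per-period co-occurrence networks with
#' transitivity and bootstrap CIs -> per-period documents, LDA with
#' coherence grid, topic summaries and topic networks -> topic-vs-
#' keyword overlap per period. All declared outputs are written under
#' `outdir` together with `manifest.json` (inputs, seeds, settings,
#' output list).
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if needed).
#' @return list of class `pipeline_result` with all intermediate
#'   objects and `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  out <- function(name) file.path(outdir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- ingest -----------------------------------------------------------
  ingest <- stage("ingest", {
    if (!is.null(config$corpus_csv)) {
      corpus <- read_publications(config$corpus_csv)
      synonyms <- if (!is.null(config$synonym_tsv)) {
        read_synonym_map(config$synonym_tsv)
      } else {
        synonym_map()
      }
      list(corpus = corpus, synonyms = synonyms)
    } else {
      gen <- generate_corpus(config$synth)
      list(corpus = gen$corpus, synonyms = gen$synonyms, truth = gen$truth)
    }
  })

  corpus <- stage("year_filter",
                  filter_years_by_min_count(ingest$corpus, config$min_per_year))
  norm <- stage("normalize", normalize_corpus(corpus, ingest$synonyms))

  # --- trends -----------------------------------------------------------
  counts <- annual_counts(corpus)
  growth <- stage("growth_fit", fit_exponential(counts))
  readr::write_tsv(
    tibble::tibble(year = as.integer(names(counts)), count = as.integer(counts)),
    out("annual_counts.tsv"), progress = FALSE
  )
  jsonlite::write_json(
    list(a = growth$a, b = growth$b, r_squared = growth$r_squared,
         n = growth$n, doubling_time = growth$doubling_time,
         x_origin = growth$x_origin),
    out("growth_fit.json"), auto_unbox = TRUE, digits = NA
  )

  # --- periods and top keywords ----------------------------------------
  periods <- split_by_period(norm, config$boundary_year)
  tops <- lapply(periods, top_keywords, k = config$top_k, exclude = config$exclude)
  union_kw <- union_keywords(tops$pre, tops$post)

  # --- year clustering --------------------------------------------------
  mat <- stage("build_matrix", build_matrix(norm, union_kw))
  clustering <- stage("ward_cluster", ward_cluster_years(mat))
  write_dendrogram_newick(clustering, out("year_dendrogram.nwk"))
  merges <- clustering$tree$merge
  readr::write_tsv(
    tibble::tibble(step = seq_len(nrow(merges)), left = merges[, 1],
                   right = merges[, 2], height = clustering$tree$height),
    out("year_merge_table.tsv"), progress = FALSE
  )
  # heatmap matrix, year columns in dendrogram (cluster) order
  ord <- clustering$tree$order
  heat <- tibble::as_tibble(mat$values[, ord, drop = FALSE], rownames = "keyword")
  readr::write_tsv(heat, out("keyword_matrix.tsv"), progress = FALSE)

  stability <- stage("cluster_stability", bootstrap_cluster_stability(
    mat, n_boot = config$n_boot, n_clusters = config$n_clusters,
    seed = stage_seed(config, 101L)
  ))
  readr::write_tsv(
    tibble::tibble(cluster = names(stability), mean_jaccard = unname(stability)),
    out("cluster_stability.tsv"), progress = FALSE
  )
  enr <- stage("enrichment",
               enrichment(mat, clustering, config$n_clusters, config$enrich_top_n))
  readr::write_tsv(enr$top, out("cluster_enrichment.tsv"), progress = FALSE)

  # --- keyword co-occurrence networks ----------------------------------
  conet <- lapply(c(pre = "pre", post = "post"), function(p) {
    stats <- compute_cooccurrence(periods[[p]], tops[[p]])
    net <- build_network(stats)
    ci <- bootstrap_transitivity_ci(
      periods[[p]], tops[[p]], n_boot = config$n_boot,
      level = config$ci_level,
      seed = stage_seed(config, if (p == "pre") 201L else 202L)
    )
    list(stats = stats, net = net,
         transitivity = global_transitivity(net), ci = ci)
  })
  write_edgelist_tsv(conet$pre$net, out("keyword_network_pre.tsv"), conet$pre$stats)
  write_edgelist_tsv(conet$post$net, out("keyword_network_post.tsv"), conet$post$stats)
  jsonlite::write_json(
    list(
      pre = list(transitivity = conet$pre$transitivity,
                 ci_low = conet$pre$ci$low, ci_high = conet$pre$ci$high),
      post = list(transitivity = conet$post$transitivity,
                  ci_low = conet$post$ci$low, ci_high = conet$post$ci$high)
    ),
    out("keyword_transitivity.json"), auto_unbox = TRUE, digits = NA
  )

  # --- topic modeling ---------------------------------------------------
  raw_periods <- split_by_period(corpus, config$boundary_year)
  topics <- lapply(c(pre = "pre", post = "post"), function(p) {
    docs <- build_documents(raw_periods[[p]])
    sel <- select_k(
      docs, candidate_ks = config$k_grid,
      seed = stage_seed(config, if (p == "pre") 301L else 302L),
      iterations = config$lda_iterations,
      top_n = config$summary_top_n,
      chosen_k = config$chosen_k
    )
    model <- sel$models[[as.character(sel$chosen_k)]]
    summaries <- topic_top_words(model, n = config$summary_top_n)
    net <- topic_word_network(summaries, top_n = config$network_top_n)
    list(documents = docs, selection = sel, model = model,
         summaries = summaries, net = net,
         transitivity = global_transitivity(net))
  })
  readr::write_tsv(
    dplyr::bind_rows(
      dplyr::mutate(topics$pre$selection$scores, period = "pre"),
      dplyr::mutate(topics$post$selection$scores, period = "post")
    ),
    out("lda_coherence.tsv"), progress = FALSE
  )
  write_topic_summaries(topics$pre$summaries,
                        path_json = out("topic_summaries_pre.json"))
  write_topic_summaries(topics$post$summaries,
                        path_json = out("topic_summaries_post.json"))

  # --- topic vs keyword network comparison ------------------------------
  overlaps <- lapply(c(pre = "pre", post = "post"), function(p) {
    overlap_report(subject = topics[[p]]$net, reference = conet[[p]]$net)
  })
  jsonlite::write_json(
    list(
      pre = list(node_overlap = overlaps$pre$nodes$fraction,
                 edge_overlap = overlaps$pre$edges$fraction,
                 topic_transitivity = topics$pre$transitivity),
      post = list(node_overlap = overlaps$post$nodes$fraction,
                  edge_overlap = overlaps$post$edges$fraction,
                  topic_transitivity = topics$post$transitivity)
    ),
    out("network_overlap.json"), auto_unbox = TRUE, digits = NA
  )

  outputs <- c(
    "annual_counts.tsv", "growth_fit.json", "keyword_matrix.tsv",
    "year_dendrogram.nwk", "year_merge_table.tsv", "cluster_stability.tsv",
    "cluster_enrichment.tsv", "keyword_network_pre.tsv",
    "keyword_network_post.tsv", "keyword_transitivity.json",
    "lda_coherence.tsv", "topic_summaries_pre.json",
    "topic_summaries_post.json", "network_overlap.json"
  )
  manifest <- list(
    package = "beemine",
    version = as.character(utils::packageVersion("beemine")),
    seed = config$seed,
    inputs = list(
      corpus_csv = config$corpus_csv, synonym_tsv = config$synonym_tsv,
      synthetic = is.null(config$corpus_csv)
    ),
    settings = config[c("boundary_year", "min_per_year", "top_k", "exclude",
                        "n_clusters", "enrich_top_n", "n_boot", "ci_level",
                        "k_grid", "chosen_k", "lda_iterations",
                        "summary_top_n", "network_top_n")],
    outputs = outputs
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  structure(
    list(
      corpus = corpus, normalized = norm, synonyms = ingest$synonyms,
      truth = ingest$truth, growth = growth, periods = periods,
      top_keywords = tops, union_keywords = union_kw,
      matrix = mat, clustering = clustering, stability = stability,
      enrichment = enr, conet = conet, topics = topics,
      overlaps = overlaps, manifest = manifest, outdir = outdir
    ),
    class = "pipeline_result"
  )
}
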