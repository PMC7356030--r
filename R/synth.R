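#' Synthetic bibliographic corpora with known ground truth
#'
#' Emulates the structure of a honey-bee literature export: annual
#' publication counts growing exponentially, an era change in topic
#' emphasis at a regime year, per-publication author keywords drawn
#' from planted topic vocabularies (with lexical variants injected at a
#' known rate and recorded in a synonym map), and bag-of-words titles
#' and abstracts drawn from the same topic mixtures. Because the
#' generating parameters are known, every pipeline stage has a
#' recoverable truth: the growth rate, the regime year, the within-topic
#' co-occurrence structure, and the topic vocabularies themselves.
#'
#' @name synth
NULL

# default planted topics: bee-domain vocabularies, era 1 emphasising
# behavior/taxonomy/pollination/products/physiology, era 2 shifting to
# health, genomics and toxicology. "bee" and "colony" are deliberately
# shared across all topics, as ubiquitous terms are in real abstracts.
default_topics <- function() {
  list(
    behavior = c("foraging", "dance", "behavior", "communication", "learning",
                 "memory", "orientation", "recruitment", "vision",
                 "division of labor"),
    taxonomy = c("hymenoptera", "subspecies", "morphology", "apis cerana",
                 "africanized", "taxonomy", "drone", "queen", "caste",
                 "anatomy"),
    pollination = c("pollination", "crops", "flowers", "nectar", "pollinator",
                    "seed", "orchard", "bloom", "fruit", "yield"),
    products = c("honey", "pollen", "propolis", "royal jelly", "venom", "wax",
                 "beekeeping", "hive", "apiary", "harvest"),
    physiology = c("pheromone", "gland", "hormone", "metabolism", "enzyme",
                   "protein", "larvae", "development", "reproduction", "ovary"),
    health = c("varroa", "mite", "pathogen", "virus", "nosema", "infection",
               "immunity", "disease", "colony collapse disorder", "parasite"),
    genomics = c("genome", "gene", "expression", "sequencing", "transcriptome",
                 "pcr", "microarray", "methylation", "genotype", "allele"),
    toxicology = c("pesticide", "neonicotinoid", "toxicity", "insecticide",
                   "residue", "exposure", "imidacloprid", "mortality",
                   "contamination", "risk")
  )
}

default_era_weights <- function(n_topics = 8L) {
  w <- rbind(
    era1 = c(0.22, 0.18, 0.18, 0.18, 0.16, 0.03, 0.02, 0.03),
    era2 = c(0.10, 0.06, 0.12, 0.10, 0.10, 0.22, 0.18, 0.12)
  )
  if (n_topics != 8L) stop("default era weights assume 8 topics")
  w
}

#' Configuration for the synthetic corpus generator
#'
#' @param years integer vector of calendar years (default 1957:2017,
#'   the span of the emulated export).
#' @param amplitude expected publications in the first year (default
#'   6.29).
#' @param rate exponential growth rate per year (default 0.087/yr,
#'   a doubling time just under 8 years, typical of a growing
#'   biological subfield).
#' @param regime_year first year of the second era (default 1992; era
#'   membership switches topic emphasis).
#' @param topics named list of character vectors: each topic's
#'   vocabulary, most prominent first (within-topic word probabilities
#'   decay as 1/rank). Entries may be multi-word phrases.
#' @param era_weights 2 x n_topics matrix of era-level topic weights
#'   (rows sum to 1).
#' @param concentration Dirichlet concentration scaling the era
#'   weights into per-document topic mixtures (default 0.8: documents
#'   lean on a few topics, as real abstracts do).
#' @param keywords_per_pub inclusive range of author keywords per
#'   publication (default 3 to 8).
#' @param title_length,abstract_length inclusive token-count ranges
#'   (defaults 5-12 and 40-80).
#' @param variant_rate probability that an emitted keyword is replaced
#'   by a registered lexical variant (default 0.1); every injected
#'   variant is recorded in the emitted synonym map.
#' @param search_term_rate probability a publication carries the
#'   search-term keyword "apis mellifera" (default 0.9); it dominates
#'   the keyword ranking exactly as a query term does in a real
#'   export.
#' @param seed integer RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(years = 1957:2017,
                         amplitude = 6.29,
                         rate = 0.087,
                         regime_year = 1992L,
                         topics = default_topics(),
                         era_weights = default_era_weights(length(topics)),
                         concentration = 0.8,
                         keywords_per_pub = c(3L, 8L),
                         title_length = c(5L, 12L),
                         abstract_length = c(40L, 80L),
                         variant_rate = 0.1,
                         search_term_rate = 0.9,
                         seed = 1L) {
  stopifnot(
    rate >= 0, amplitude > 0,
    regime_year >= min(years), regime_year <= max(years) + 1L,
    is.list(topics), length(topics) >= 1,
    nrow(era_weights) == 2L, ncol(era_weights) == length(topics),
    concentration > 0,
    variant_rate >= 0, variant_rate <= 1,
    search_term_rate >= 0, search_term_rate <= 1
  )
  era_weights <- era_weights / rowSums(era_weights)
  structure(
    list(
      years = as.integer(years), amplitude = amplitude, rate = rate,
      regime_year = as.integer(regime_year), topics = topics,
      era_weights = era_weights, concentration = concentration,
      keywords_per_pub = keywords_per_pub, title_length = title_length,
      abstract_length = abstract_length, variant_rate = variant_rate,
      search_term_rate = search_term_rate, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# 1/rank word probabilities within a topic
topic_word_probs <- function(words) {
  p <- 1 / seq_along(words)
  p / sum(p)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

variant_forms <- function(kw) {
  c(paste0("honey bee ", kw), paste0(kw, " in apis mellifera"))
}

#' Generate a synthetic corpus
#'
#' @param config a [synth_config()].
#' @return list with `corpus` (a `bee_corpus`), `synonyms` (the
#'   [synonym_map()] of injected variants), and `truth`: the expected
#'   (unrounded) and realized annual count curves, era label per year,
#'   per-publication topic mixtures, and the generating topic of every
#'   topic-exclusive keyword.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  years <- config$years
  x <- years - min(years)
  true_curve <- config$amplitude * exp(config$rate * x)
  counts <- round(true_curve)
  if (all(counts == 0)) stop("degenerate config: all annual counts are zero")

  topics <- config$topics
  topic_names <- names(topics)
  word_probs <- lapply(topics, topic_word_probs)

  # keyword -> generating topic, for keywords unique to one topic
  all_kws <- unlist(topics, use.names = FALSE)
  exclusive <- names(which(table(all_kws) == 1L))
  kw_topic <- stats::setNames(
    rep(topic_names, lengths(topics)), all_kws
  )[exclusive]

  n_total <- sum(counts)
  pub_years <- rep(years, counts)
  era <- ifelse(pub_years < config$regime_year, 1L, 2L)

  titles <- character(n_total)
  abstracts <- character(n_total)
  keyword_sets <- vector("list", n_total)
  mixtures <- base::matrix(0, n_total, length(topics),
                           dimnames = list(NULL, topic_names))
  variants_seen <- character(0)

  draw_words <- function(theta, n) {
    z <- sample.int(length(topics), n, replace = TRUE, prob = theta)
    out <- character(n)
    for (t in unique(z)) {
      idx <- which(z == t)
      out[idx] <- sample(topics[[t]], length(idx), replace = TRUE,
                         prob = word_probs[[t]])
    }
    out
  }

  for (i in seq_len(n_total)) {
    theta <- rdirichlet1(config$concentration * config$era_weights[era[i], ])
    mixtures[i, ] <- theta

    n_kw <- sample(config$keywords_per_pub[1]:config$keywords_per_pub[2], 1L)
    kws <- unique(draw_words(theta, n_kw))
    inject <- stats::runif(length(kws)) < config$variant_rate
    if (any(inject)) {
      for (j in which(inject)) {
        forms <- variant_forms(kws[j])
        form <- forms[sample.int(length(forms), 1L)]
        variants_seen <- c(variants_seen, stats::setNames(kws[j], form))
        kws[j] <- form
      }
    }
    if (stats::runif(1) < config$search_term_rate) {
      kws <- c("apis mellifera", kws)
    }

    n_title <- sample(config$title_length[1]:config$title_length[2], 1L)
    n_abs <- sample(config$abstract_length[1]:config$abstract_length[2], 1L)
    titles[i] <- paste(draw_words(theta, n_title), collapse = " ")
    abstracts[i] <- paste(draw_words(theta, n_abs), collapse = " ")
    keyword_sets[[i]] <- kws
  }

  corpus <- bee_corpus(tibble::tibble(
    id = sprintf("synth%06d", seq_len(n_total)),
    year = pub_years,
    title = titles,
    abstract = abstracts,
    keywords = keyword_sets
  ))
  variants_seen <- variants_seen[!duplicated(names(variants_seen))]
  synonyms <- synonym_map(names(variants_seen), unname(variants_seen))
  truth <- list(
    true_curve = stats::setNames(true_curve, years),
    annual_counts = stats::setNames(as.numeric(counts), years),
    era_by_year = stats::setNames(
      ifelse(years < config$regime_year, 1L, 2L), years
    ),
    regime_year = config$regime_year,
    rate = config$rate,
    amplitude = config$amplitude,
    mixtures = mixtures,
    keyword_topics = kw_topic,
    topics = topics
  )
  list(corpus = corpus, synonyms = synonyms, truth = truth)
}

#' Write a synthetic corpus as pipeline-ready fixture files
#'
#' Emits the corpus in the Scopus CSV dialect plus the injected
#' synonym map (TSV) and the ground truth (JSON) into a directory, so
#' [read_publications()] round-trips it.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return named list of the three file paths, invisibly; the
#'   generated objects are attached as attribute `"generated"`.
#' @export
emit_fixture <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_corpus(config)
  paths <- list(
    corpus = file.path(dir, "corpus.csv"),
    synonyms = file.path(dir, "synonyms.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_publications(gen$corpus, paths$corpus)
  write_synonym_map(gen$synonyms, paths$synonyms)
  truth <- gen$truth
  truth$mixtures <- NULL  # bulky; regenerable from the seed
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  out <- paths
  attr(out, "generated") <- gen
  invisible(out)
}
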