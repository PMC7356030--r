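#' Topic modeling of titles, keywords, and abstracts
#'
#' Publications are turned into cleaned bag-of-words documents
#' (title + keywords + abstract; punctuation, numbers, and short or
#' stop tokens removed; Porter-stemmed), modeled with latent Dirichlet
#' allocation via a collapsed Gibbs sampler, and scored with the c_v
#' coherence metric to choose the number of topics.
#'
#' @name topics
NULL

# Snowball English stop-word list
.stopwords_en <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
  "your", "yours", "yourself", "yourselves", "he", "him", "his",
  "himself", "she", "her", "hers", "herself", "it", "its", "itself",
  "they", "them", "their", "theirs", "themselves", "what", "which",
  "who", "whom", "this", "that", "these", "those", "am", "is", "are",
  "was", "were", "be", "been", "being", "have", "has", "had", "having",
  "do", "does", "did", "doing", "would", "should", "could", "ought",
  "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
  "while", "of", "at", "by", "for", "with", "about", "against",
  "between", "into", "through", "during", "before", "after", "above",
  "below", "to", "from", "up", "down", "in", "out", "on", "off",
  "over", "under", "again", "further", "then", "once", "here", "there",
  "when", "where", "why", "how", "all", "any", "both", "each", "few",
  "more", "most", "other", "some", "such", "no", "nor", "not", "only",
  "own", "same", "so", "than", "too", "very", "can", "will", "just",
  "don", "now"
)

#' Build cleaned bag-of-words documents
#'
#' Concatenates title, author keywords, and abstract; lowercases;
#' treats every non-alphanumeric character as a separator; drops
#' numeric tokens (including decimal and exponent notation fragments),
#' tokens shorter than two characters, and (by default) standard
#' English stop words; Porter-stems what remains.
#'
#' @param corpus a `bee_corpus` (raw keywords are fine; they are part
#'   of the text here, not a curated field).
#' @param remove_stopwords drop standard English stop words (default
#'   `TRUE`).
#' @param min_token_length minimum token length kept (default 2).
#' @return tibble with columns `id`, `year`, `tokens` (list of
#'   character vectors).
#' @export
build_documents <- function(corpus, remove_stopwords = TRUE, min_token_length = 2L) {
  text <- paste(
    corpus$records$title,
    vapply(corpus$records$keywords, paste, character(1), collapse = " "),
    corpus$records$abstract
  )
  tokens <- lapply(tolower(text), clean_tokens,
                   remove_stopwords = remove_stopwords,
                   min_token_length = min_token_length)
  tibble::tibble(
    id = corpus$records$id,
    year = corpus$records$year,
    tokens = tokens
  )
}

clean_tokens <- function(text, remove_stopwords = TRUE, min_token_length = 2L) {
  text <- gsub("[^a-z0-9]+", " ", text)
  toks <- strsplit(trimws(text), " ", fixed = TRUE)[[1]]
  toks <- toks[!grepl("[0-9]", toks)]
  toks <- toks[nchar(toks) >= min_token_length]
  if (remove_stopwords) toks <- toks[!toks %in% .stopwords_en]
  if (!length(toks)) return(character(0))
  porter_stem(toks)
}

#' Train an LDA topic model
#'
#' Collapsed Gibbs sampling with symmetric Dirichlet priors. The
#' returned topic-word (`phi`) and document-topic (`theta`) matrices
#' are posterior means averaged over the last `n_avg` sweeps of a
#' single chain. Fully deterministic under a fixed seed (the sampler
#' keeps its own RNG stream).
#'
#' @param documents tibble from [build_documents()].
#' @param k number of topics (1 <= k <= vocabulary size).
#' @param seed integer seed for the sampler.
#' @param iterations Gibbs sweeps (default 200).
#' @param alpha document-topic concentration; default `1/k`.
#' @param eta topic-word concentration; default 0.01.
#' @param n_avg sweeps averaged for the point estimate (default 20).
#' @return list of class `lda_model`: `k`, `phi` (k x V), `theta`
#'   (D x k), `vocab`, `word_freq` (empirical corpus frequencies),
#'   and training metadata.
#' @export
train_lda <- function(documents, k, seed = 1L, iterations = 200L,
                      alpha = NULL, eta = 0.01, n_avg = 20L) {
  stopifnot(k >= 1)
  if (is.null(alpha)) alpha <- 1 / k
  vocab <- sort(unique(unlist(documents$tokens, use.names = FALSE)))
  if (!length(vocab)) stop("vocabulary is empty")
  if (k > length(vocab)) stop("k exceeds vocabulary size")
  docs_ids <- lapply(documents$tokens, function(t) match(t, vocab) - 1L)
  keep <- lengths(docs_ids) > 0L
  fit <- lda_gibbs_cpp(docs_ids[keep], length(vocab), as.integer(k),
                       alpha, eta, as.integer(iterations),
                       as.integer(n_avg), as.integer(seed))
  phi <- fit$phi
  dimnames(phi) <- list(paste0("topic", seq_len(k)), vocab)
  theta <- base::matrix(NA_real_, nrow = nrow(documents), ncol = k,
                        dimnames = list(documents$id, paste0("topic", seq_len(k))))
  theta[keep, ] <- fit$theta
  theta[!keep, ] <- 1 / k   # empty documents carry the prior mean
  tok_counts <- table(factor(unlist(documents$tokens, use.names = FALSE), levels = vocab))
  structure(
    list(
      k = k, phi = phi, theta = theta, vocab = vocab,
      word_freq = as.numeric(tok_counts) / sum(tok_counts),
      alpha = alpha, eta = eta,
      iterations = iterations, n_avg = n_avg, seed = seed,
      inference = "collapsed Gibbs"
    ),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf(
    "<lda_model> k = %d, vocabulary %d, %s (%d sweeps, seed %d)\n",
    x$k, length(x$vocab), x$inference, x$iterations, x$seed
  ))
  invisible(x)
}

#' c_v topic coherence
#'
#' Boolean sliding-window co-occurrence counts (window width 110;
#' documents shorter than the window contribute one window) give
#' probabilities from which each top word receives an NPMI vector over
#' the topic's top-word set; coherence per topic is the mean cosine
#' similarity between each word's vector and the vector sum of the set
#' (one-versus-all segmentation), and the model score is the mean over
#' topics. A top word absent from every window gets a +1 smoothed
#' count rather than an error.
#'
#' @param model an `lda_model`.
#' @param documents tibble from [build_documents()] (typically the
#'   training documents).
#' @param top_n words per topic entering the score (default 10).
#' @param window sliding-window width (default 110).
#' @return coherence score (higher is more coherent; in [0, 1] in
#'   practice).
#' @export
coherence_cv <- function(model, documents, top_n = 10L, window = 110L) {
  stopifnot(top_n >= 2)
  summaries <- topic_top_words(model, n = top_n)
  per_topic <- vapply(
    split(summaries$word, summaries$topic),
    function(words) topic_cv(words, documents$tokens, window),
    numeric(1)
  )
  mean(per_topic)
}

topic_cv <- function(words, token_lists, window) {
  words <- unique(words)
  nw <- length(words)
  counts <- base::matrix(0, nw, nw, dimnames = list(words, words))
  n_windows <- 0
  for (toks in token_lists) {
    nt <- length(toks)
    if (!nt) next
    starts <- if (nt <= window) 1L else seq_len(nt - window + 1L)
    for (s in starts) {
      present <- words %in% toks[s:min(s + window - 1L, nt)]
      counts <- counts + tcrossprod(as.numeric(present))
      n_windows <- n_windows + 1
    }
  }
  if (n_windows == 0) return(0)
  # +1 smoothing for words never observed in any window
  missing <- diag(counts) == 0
  if (any(missing)) diag(counts)[missing] <- 1
  p_w <- diag(counts) / n_windows
  p_ij <- counts / n_windows
  eps <- 1e-12
  npmi <- log((p_ij + eps) / outer(p_w, p_w)) / -log(p_ij + eps)
  v_all <- colSums(npmi)
  cos_sim <- vapply(seq_len(nw), function(i) {
    num <- sum(npmi[i, ] * v_all)
    den <- sqrt(sum(npmi[i, ]^2)) * sqrt(sum(v_all^2))
    if (den == 0) 0 else num / den
  }, numeric(1))
  mean(cos_sim)
}

#' Train models over a k-grid and pick the most coherent
#'
#' Trains one model per candidate k, scores each with c_v coherence,
#' and (by default) selects the argmax; a `chosen_k` override lets the
#' analyst blend the automated score with manual topic inspection.
#'
#' @param documents tibble from [build_documents()].
#' @param candidate_ks integer vector of topic counts
#'   (default `c(20, 50, 70, 90, 110, 140)`).
#' @param seed sampler seed (shared across candidates so the grid is
#'   comparable).
#' @param iterations Gibbs sweeps per model.
#' @param top_n top words per topic in the coherence score.
#' @param chosen_k optional manual override of the selection.
#' @param ... further arguments to [train_lda()].
#' @return list: `scores` (tibble k/coherence), `chosen_k`, `models`
#'   (named list of `lda_model`s).
#' @export
select_k <- function(documents, candidate_ks = c(20L, 50L, 70L, 90L, 110L, 140L),
                     seed = 1L, iterations = 200L, top_n = 10L,
                     chosen_k = NULL, ...) {
  stopifnot(length(candidate_ks) >= 1)
  models <- lapply(candidate_ks, function(k) {
    train_lda(documents, k = k, seed = seed, iterations = iterations, ...)
  })
  names(models) <- candidate_ks
  scores <- tibble::tibble(
    k = as.integer(candidate_ks),
    coherence = vapply(models, coherence_cv, numeric(1),
                       documents = documents, top_n = top_n)
  )
  if (is.null(chosen_k)) {
    chosen_k <- scores$k[which.max(scores$coherence)]
  } else if (!chosen_k %in% candidate_ks) {
    stop("chosen_k must be one of the candidates")
  }
  list(scores = scores, chosen_k = as.integer(chosen_k), models = models)
}

#' Ranked top words per topic
#'
#' Words are ranked by LDAvis-style relevance:
#' `lambda * log p(w|topic) + (1 - lambda) * log[p(w|topic) / p(w)]`,
#' with `p(w)` the empirical corpus frequency. `lambda = 1` (the
#' default) is plain within-topic probability; `lambda = 0` is pure
#' lift, promoting topic-exclusive words.
#'
#' @param model an `lda_model`.
#' @param n words per topic.
#' @param lambda relevance weight in [0, 1].
#' @return tibble: `topic`, `rank`, `word`, `score` (scores
#'   non-increasing within topic; ties broken lexicographically).
#' @export
topic_top_words <- function(model, n = 10L, lambda = 1) {
  stopifnot(n >= 1, n <= length(model$vocab), lambda >= 0, lambda <= 1)
  p_w <- model$word_freq
  dplyr::bind_rows(lapply(seq_len(model$k), function(t) {
    p_wt <- model$phi[t, ]
    score <- lambda * log(p_wt) + (1 - lambda) * log(p_wt / p_w)
    ord <- order(-score, model$vocab)
    take <- ord[seq_len(n)]
    tibble::tibble(
      topic = t,
      rank = seq_len(n),
      word = model$vocab[take],
      score = unname(score[take])
    )
  }))
}

#' Topic-word co-occurrence network
#'
#' Each topic's top-n words form a clique; cliques are merged over the
#' shared vocabulary, so topics sharing a word join into one component
#' through it. Edge weight counts the topics in which the pair
#' co-occurs.
#'
#' @param summaries tibble from [topic_top_words()].
#' @param top_n words per topic used as nodes (default 5).
#' @return an undirected weighted `igraph` graph.
#' @export
topic_word_network <- function(summaries, top_n = 5L) {
  stopifnot(top_n >= 2)
  use <- summaries[summaries$rank <= top_n, ]
  nodes <- sort(unique(use$word))
  edge_tab <- new.env(parent = emptyenv())
  for (t in unique(use$topic)) {
    words <- sort(unique(use$word[use$topic == t]))
    if (length(words) < 2L) next
    pairs <- utils::combn(words, 2L)
    for (j in seq_len(ncol(pairs))) {
      key <- paste(pairs[1, j], pairs[2, j], sep = "\r")
      edge_tab[[key]] <- (edge_tab[[key]] %||% 0) + 1
    }
  }
  keys <- ls(edge_tab)
  if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- tibble::tibble(
      from = vapply(parts, `[`, character(1), 1L),
      to = vapply(parts, `[`, character(1), 2L),
      weight = vapply(keys, function(k) edge_tab[[k]], numeric(1))
    )
  } else {
    edges <- tibble::tibble(from = character(0), to = character(0),
                            weight = numeric(0))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Export topic summaries
#'
#' @param summaries tibble from [topic_top_words()].
#' @param path_json,path_tsv optional output paths (either may be
#'   `NULL`).
#' @return invisibly, a list of per-topic records as written to JSON.
#' @export
write_topic_summaries <- function(summaries, path_json = NULL, path_tsv = NULL) {
  recs <- lapply(split(summaries, summaries$topic), function(df) {
    list(topic = df$topic[1], words = df$word, scores = df$score)
  })
  names(recs) <- NULL
  if (!is.null(path_json)) {
    jsonlite::write_json(recs, path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_tsv)) readr::write_tsv(summaries, path_tsv, progress = FALSE)
  invisible(recs)
}

#' Static HTML table of topic summaries
#'
#' A plain, dependency-free table export for browsing topics outside R.
#'
#' @param summaries tibble from [topic_top_words()].
#' @param path output `.html` path.
#' @return `path`, invisibly.
#' @export
write_topics_html <- function(summaries, path) {
  rows <- vapply(split(summaries, summaries$topic), function(df) {
    sprintf("<tr><td>%d</td><td>%s</td></tr>", df$topic[1],
            paste(df$word, collapse = ", "))
  }, character(1))
  writeLines(c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"><title>Topics</title></head><body>",
    "<table border=\"1\"><tr><th>Topic</th><th>Top words</th></tr>",
    rows,
    "</table></body></html>"
  ), path)
  invisible(path)
}
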