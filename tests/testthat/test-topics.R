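test_that("document cleaning strips numbers, punctuation, short and stop tokens, then stems", {
  corpus <- mini_corpus(
    2010,
    keywords = list(character(0)),
    titles = "RNA-seq of Apis mellifera (n=10, p<0.05)"
  )
  docs <- build_documents(corpus)
  expect_equal(docs$tokens[[1]], c("rna", "seq", "api", "mellifera"))

  corpus2 <- mini_corpus(2010, keywords = list("Varroa destructor"))
  expect_equal(build_documents(corpus2)$tokens[[1]], c("varroa", "destructor"))

  # empty abstract: tokens come from title and keywords only
  corpus3 <- mini_corpus(2010, keywords = list("pollen"), titles = "Nectar foraging")
  expect_equal(build_documents(corpus3)$tokens[[1]], c("nectar", "forag", "pollen"))

  # stop-word removal is configurable
  with_stops <- build_documents(
    mini_corpus(2010, titles = "the bees and the flowers"),
    remove_stopwords = FALSE
  )
  expect_true("the" %in% with_stops$tokens[[1]])
})

planted_docs <- function(n_docs = 150, seed = 21, n_topics = 3, words_per_doc = 40) {
  vocabs <- lapply(seq_len(n_topics), function(t) {
    sprintf("t%dword%02d", t, 1:20)
  })
  set.seed(seed)
  tokens <- lapply(seq_len(n_docs), function(i) {
    t <- (i %% n_topics) + 1
    sample(vocabs[[t]], words_per_doc, replace = TRUE)
  })
  list(
    docs = tibble::tibble(
      id = sprintf("d%03d", seq_len(n_docs)),
      year = 2000L,
      tokens = tokens
    ),
    vocabs = vocabs
  )
}

test_that("LDA is deterministic under a fixed seed and validates inputs", {
  pd <- planted_docs(60)
  m1 <- train_lda(pd$docs, k = 3, seed = 9, iterations = 60)
  m2 <- train_lda(pd$docs, k = 3, seed = 9, iterations = 60)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$theta, m2$theta)
  m3 <- train_lda(pd$docs, k = 3, seed = 10, iterations = 60)
  expect_false(identical(m1$phi, m3$phi))
  expect_error(train_lda(pd$docs, k = 10000), "vocabulary")
  # distributions normalize
  expect_equal(unname(rowSums(m1$phi)), rep(1, 3), tolerance = 1e-6)
  expect_equal(unname(rowSums(m1$theta)), rep(1, nrow(pd$docs)), tolerance = 1e-6)
})

test_that("a one-topic model recovers corpus unigram frequencies", {
  pd <- planted_docs(80, seed = 33)
  m <- train_lda(pd$docs, k = 1, seed = 2, iterations = 40)
  emp <- table(factor(unlist(pd$docs$tokens), levels = m$vocab))
  emp <- as.numeric(emp) / sum(emp)
  expect_lt(sum(abs(m$phi[1, ] - emp)) / 2, 0.01)  # total variation
})

test_that("two disjoint-vocabulary topics are recovered cleanly at k = 2", {
  pd <- planted_docs(120, seed = 5, n_topics = 2)
  m <- train_lda(pd$docs, k = 2, seed = 4, iterations = 120)
  tops <- topic_top_words(m, n = 10)
  for (t in 1:2) {
    words <- tops$word[tops$topic == t]
    origin <- unique(substr(words, 1, 2))
    expect_length(origin, 1)  # all ten from one generating vocabulary
  }
})

test_that("c_v coherence separates co-occurring from never-co-occurring top words", {
  pd <- planted_docs(90, seed = 6, n_topics = 3)
  good <- train_lda(pd$docs, k = 3, seed = 8, iterations = 100)
  score_good <- coherence_cv(good, pd$docs, top_n = 8)
  # scramble: a fake model whose "topics" mix words that never share a document
  fake <- good
  mixed_vocab <- c(pd$vocabs[[1]][1:4], pd$vocabs[[2]][1:3], pd$vocabs[[3]][1:3])
  fake$phi[1, ] <- 0
  fake$phi[1, match(mixed_vocab, fake$vocab)] <- 1 / 10
  fake$phi[2, ] <- fake$phi[1, ]
  fake$phi[3, ] <- fake$phi[1, ]
  score_bad <- coherence_cv(fake, pd$docs, top_n = 8)
  expect_gt(score_good, score_bad)
  expect_gte(score_good, 0)
  expect_lte(score_good, 1)
})

test_that("select_k scores each candidate and honors the manual override", {
  pd <- planted_docs(60, seed = 14)
  sel <- select_k(pd$docs, candidate_ks = c(3), seed = 3, iterations = 40)
  expect_equal(sel$chosen_k, 3L)
  expect_equal(nrow(sel$scores), 1)
  sel2 <- select_k(pd$docs, candidate_ks = c(2, 3), seed = 3, iterations = 40,
                   chosen_k = 2)
  expect_equal(sel2$chosen_k, 2L)
  expect_error(
    select_k(pd$docs, candidate_ks = c(2, 3), seed = 3, iterations = 10,
             chosen_k = 7),
    "candidates"
  )
})

test_that("top-word ranking follows the relevance interpolation", {
  # hand-built model: 2 topics over 4 words; word 'common' is globally
  # frequent, word 'niche1' is exclusive to topic 1
  vocab <- c("common", "niche1", "niche2", "rare")
  phi <- rbind(
    c(0.55, 0.40, 0.015, 0.035),
    c(0.60, 0.015, 0.35, 0.035)
  )
  dimnames(phi) <- list(c("topic1", "topic2"), vocab)
  model <- structure(
    list(k = 2L, phi = phi, vocab = vocab,
         word_freq = c(0.6, 0.2, 0.15, 0.05)),
    class = "lda_model"
  )
  # lambda = 1: plain within-topic probability puts 'common' first
  r1 <- topic_top_words(model, n = 2, lambda = 1)
  expect_equal(r1$word[r1$topic == 1], c("common", "niche1"))
  expect_true(all(diff(r1$score[r1$topic == 1]) <= 0))
  # lambda = 0: pure lift promotes the topic-exclusive word
  r0 <- topic_top_words(model, n = 2, lambda = 0)
  expect_equal(r0$word[r0$topic == 1][1], "niche1")
})

test_that("topic networks are merged cliques with shared-word connectors", {
  summaries <- tibble::tibble(
    topic = rep(1:2, each = 5),
    rank = rep(1:5, 2),
    word = c("a", "b", "c", "d", "shared", "shared", "f", "g", "h", "i"),
    score = rep(seq(-1, -2, length.out = 5), 2)
  )
  net <- topic_word_network(summaries, top_n = 5)
  expect_equal(igraph::vcount(net), 9)  # 10 slots, one shared word
  expect_equal(igraph::ecount(net), 20) # two 5-cliques, no shared pair
  expect_equal(igraph::count_components(net), 1)
  # shared node bridges the cliques
  expect_equal(unname(igraph::degree(net, "shared")), 8)

  disjoint <- summaries
  disjoint$word[disjoint$topic == 2] <- c("v", "w", "x", "y", "z")
  net2 <- topic_word_network(disjoint, top_n = 5)
  expect_equal(igraph::count_components(net2), 2)
  expect_equal(igraph::vcount(net2), 10)  # = k * top_n iff nothing shared

  single <- summaries[summaries$topic == 1, ]
  net3 <- topic_word_network(single, top_n = 5)
  expect_equal(global_transitivity(net3), 1.0)

  # edge weight counts topics sharing the pair
  dup <- tibble::tibble(
    topic = rep(1:2, each = 2), rank = rep(1:2, 2),
    word = c("p", "q", "p", "q"), score = rep(c(-1, -2), 2)
  )
  net4 <- topic_word_network(dup, top_n = 2)
  expect_equal(igraph::E(net4)$weight, 2)
})

test_that("topic summary exports write JSON, TSV, and a static HTML table", {
  pd <- planted_docs(40, seed = 44)
  m <- train_lda(pd$docs, k = 2, seed = 1, iterations = 30)
  tops <- topic_top_words(m, n = 5)
  pj <- tempfile(fileext = ".json"); pt <- tempfile(fileext = ".tsv")
  ph <- tempfile(fileext = ".html")
  write_topic_summaries(tops, pj, pt)
  write_topics_html(tops, ph)
  parsed <- jsonlite::read_json(pj)
  expect_length(parsed, 2)
  expect_length(parsed[[1]]$words, 5)
  tab <- readr::read_tsv(pt, show_col_types = FALSE)
  expect_equal(nrow(tab), 10)
  expect_true(any(grepl("<table", readLines(ph))))
})
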