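#!/usr/bin/env Rscript

# Step 5: topic modeling. Builds cleaned bag-of-words documents per
# period, trains LDA over a topic-count grid, scores each model with
# c_v coherence, and exports summaries plus top-word topic networks.

suppressMessages(library(beemine))
library(readr)
library(dplyr)

seed <- 20260901L
corpus <- read_publications("results/data/corpus.csv")
corpus <- filter_years_by_min_count(corpus, 5)
periods <- split_by_period(corpus, 2006)

dir.create("results/topics", recursive = TRUE, showWarnings = FALSE)
all_scores <- list()
for (p in c("pre", "post")) {
  docs <- build_documents(periods[[p]])
  sel <- select_k(docs, candidate_ks = c(5L, 10L, 20L),
                  seed = seed + match(p, c("pre", "post")),
                  iterations = 150, chosen_k = 20L)
  all_scores[[p]] <- mutate(sel$scores, period = p)
  cat(sprintf("%s-2006 coherence by k:\n", p))
  print(sel$scores)

  model <- sel$models[[as.character(sel$chosen_k)]]
  summaries <- topic_top_words(model, n = 10)
  write_topic_summaries(
    summaries,
    path_json = sprintf("results/topics/topic_summaries_%s.json", p),
    path_tsv = sprintf("results/topics/topic_summaries_%s.tsv", p)
  )
  write_topics_html(summaries, sprintf("results/topics/topics_%s.html", p))

  net <- topic_word_network(summaries, top_n = 5)
  cat(sprintf(
    "%s-2006 topic network: %d nodes, %d edges, transitivity %.3f\n",
    p, igraph::vcount(net), igraph::ecount(net), global_transitivity(net)
  ))
  write_graphml(net, sprintf("results/topics/topic_network_%s.graphml", p))
  write_edgelist_tsv(net, sprintf("results/topics/topic_network_%s.tsv", p))
}
write_tsv(bind_rows(all_scores), "results/topics/lda_coherence.tsv")
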