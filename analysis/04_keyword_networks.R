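#!/usr/bin/env Rscript

# Step 4: keyword co-occurrence networks. Builds the per-period
# top-49 networks under the O > E independence-null edge criterion,
# computes global transitivity, and bootstraps 95% CIs.

suppressMessages(library(beemine))

seed <- 20260901L
corpus <- read_publications("results/data/corpus.csv")
corpus <- filter_years_by_min_count(corpus, 5)
norm <- normalize_corpus(corpus, read_synonym_map("results/data/synonyms.tsv"))
periods <- split_by_period(norm, 2006)

dir.create("results/networks", recursive = TRUE, showWarnings = FALSE)
trans <- list()
for (p in c("pre", "post")) {
  kws <- top_keywords(periods[[p]], k = 50, exclude = "api mellifera")
  stats <- compute_cooccurrence(periods[[p]], kws)
  net <- build_network(stats)
  t_hat <- global_transitivity(net)
  ci <- bootstrap_transitivity_ci(
    periods[[p]], kws, n_boot = 1000, level = 0.95,
    seed = seed + match(p, c("pre", "post"))
  )
  trans[[p]] <- list(transitivity = t_hat, ci_low = ci$low, ci_high = ci$high)
  cat(sprintf(
    "%s-2006 keyword network: %d nodes, %d edges, transitivity %.3f (95%% CI %.3f-%.3f)\n",
    p, igraph::vcount(net), igraph::ecount(net), t_hat, ci$low, ci$high
  ))
  write_edgelist_tsv(net, sprintf("results/networks/keyword_network_%s.tsv", p), stats)
  write_graphml(net, sprintf("results/networks/keyword_network_%s.graphml", p))
  write_gexf(net, sprintf("results/networks/keyword_network_%s.gexf", p))
}
jsonlite::write_json(trans, "results/networks/keyword_transitivity.json",
                     auto_unbox = TRUE, digits = NA)
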