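#!/usr/bin/env Rscript

# Step 6: compare the topic-word networks (computer view) against the
# keyword co-occurrence networks (author view) with exact/substring
# node and edge matching, per period.

suppressMessages(library(beemine))

dir.create("results/comparison", recursive = TRUE, showWarnings = FALSE)
for (p in c("pre", "post")) {
  topic_net <- igraph::read_graph(
    sprintf("results/topics/topic_network_%s.graphml", p), format = "graphml"
  )
  keyword_net <- igraph::read_graph(
    sprintf("results/networks/keyword_network_%s.graphml", p), format = "graphml"
  )
  rep <- overlap_report(subject = topic_net, reference = keyword_net)
  cat(sprintf(
    "%s-2006: %.0f%% of topic-network nodes and %.0f%% of edges overlap the keyword network\n",
    p, 100 * rep$nodes$fraction, 100 * rep$edges$fraction
  ))
  write_overlap_report(
    rep,
    path_json = sprintf("results/comparison/overlap_%s.json", p),
    path_tsv = sprintf("results/comparison/overlap_%s.tsv", p)
  )
}
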