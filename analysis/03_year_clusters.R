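#!/usr/bin/env Rscript

# Step 3: year clustering. Normalizes keywords, selects the top-50
# (minus the search term) per period, unions them, Ward-clusters the
# years on relative keyword frequencies, bootstraps cluster stability,
# and scores per-cluster keyword enrichment.

suppressMessages(library(beemine))
library(readr)
library(tibble)

seed <- 20260901L
corpus <- read_publications("results/data/corpus.csv")
corpus <- filter_years_by_min_count(corpus, 5)
norm <- normalize_corpus(corpus, read_synonym_map("results/data/synonyms.tsv"))

periods <- split_by_period(norm, 2006)
tops <- lapply(periods, top_keywords, k = 50, exclude = "api mellifera")
union_kw <- union_keywords(tops$pre, tops$post)
cat(sprintf(
  "top keywords: %d (pre) + %d (post) -> %d unique\n",
  length(tops$pre), length(tops$post), length(union_kw)
))

mat <- build_matrix(norm, union_kw)
clustering <- ward_cluster_years(mat)
halves <- top_split(clustering)
cat(sprintf(
  "top dendrogram split: %d-%d vs %d-%d\n",
  min(halves[[1]]), max(halves[[1]]), min(halves[[2]]), max(halves[[2]])
))

dir.create("results/clusters", recursive = TRUE, showWarnings = FALSE)
write_dendrogram_newick(clustering, "results/clusters/year_dendrogram.nwk")
ord <- clustering$tree$order
write_tsv(as_tibble(mat$values[, ord, drop = FALSE], rownames = "keyword"),
          "results/clusters/keyword_matrix.tsv")

stab <- bootstrap_cluster_stability(mat, n_boot = 1000, n_clusters = 6,
                                    seed = seed)
write_tsv(tibble(cluster = names(stab), mean_jaccard = unname(stab)),
          "results/clusters/cluster_stability.tsv")
cat("bootstrap stability (mean Jaccard) per cluster:\n")
print(round(stab, 3))

enr <- enrichment(mat, clustering, n_clusters = 6, top_n = 3)
write_tsv(enr$top, "results/clusters/cluster_enrichment.tsv")
cat("most enriched keywords per cluster:\n")
print(enr$top, n = 20)
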