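kwsets_corpus <- function(keyword_sets, year = 2000) {
  mini_corpus(rep(year, length(keyword_sets)), keywords = keyword_sets)
}

test_that("co-occurrence statistics are publication-level probabilities", {
  sets <- c(
    replicate(3, c("i", "j"), simplify = FALSE),   # both
    replicate(2, "i", simplify = FALSE),           # i only
    replicate(1, "j", simplify = FALSE),           # j only
    replicate(4, "x", simplify = FALSE)            # neither
  )
  stats <- compute_cooccurrence(kwsets_corpus(sets), c("i", "j"))
  expect_equal(stats$N, 10)
  expect_equal(unname(stats$p_i), c(0.5, 0.4))
  expect_equal(stats$O["i", "j"], 0.3)
  expect_equal(stats$E["i", "j"], 0.2)
  expect_equal(stats$n_ij, t(stats$n_ij))
  # absent keyword: all zeros
  st2 <- compute_cooccurrence(kwsets_corpus(sets), c("i", "ghost"))
  expect_equal(unname(st2$n_i["ghost"]), 0)
  expect_true(all(st2$O["ghost", ] == 0) && all(st2$E["ghost", ] == 0))
  expect_error(compute_cooccurrence(kwsets_corpus(sets), character(0)), "non-empty")
})

test_that("edges require strict observed excess over the independence expectation", {
  sets <- c(
    replicate(3, c("i", "j"), simplify = FALSE),
    replicate(2, "i", simplify = FALSE),
    replicate(1, "j", simplify = FALSE),
    replicate(4, "x", simplify = FALSE)
  )
  stats <- compute_cooccurrence(kwsets_corpus(sets), c("i", "j", "x"))
  net <- build_network(stats)
  expect_true(igraph::are_adjacent(net, "i", "j"))
  eid <- igraph::get_edge_ids(net, c("i", "j"))
  expect_equal(igraph::E(net)$weight[eid], 0.1, tolerance = 1e-12)
  # x never co-occurs: O = 0 < E, no edges, but the node stays
  expect_equal(igraph::degree(net)["x"], c(x = 0))
  expect_equal(igraph::vcount(net), 3)

  # O exactly equal to E: no edge. 2 pubs: {a,b}, {}; O = 1/2? build O=E case:
  # a and b each in 1 of 2 pubs, together in 0.5*0.5*N... use 4 pubs where
  # n_a = n_b = 2, n_ab = 1 so O = 0.25 = E
  sets_eq <- list(c("a", "b"), "a", "b", "z")
  st_eq <- compute_cooccurrence(kwsets_corpus(sets_eq), c("a", "b"))
  expect_equal(st_eq$O["a", "b"], st_eq$E["a", "b"])
  expect_equal(igraph::ecount(build_network(st_eq)), 0)
})

test_that("global transitivity matches closed-form values on canonical graphs", {
  g_triangle <- igraph::make_full_graph(3)
  expect_equal(global_transitivity(g_triangle), 1.0)
  g_path <- igraph::graph_from_literal(a - b - c)
  expect_equal(global_transitivity(g_path), 0.0)
  # triangle a-b-c plus pendant d on a: 3 closed of 5 connected triplets
  g_pendant <- igraph::graph_from_literal(a - b - c - a, a - d)
  expect_equal(global_transitivity(g_pendant), 0.6)
  expect_equal(global_transitivity(igraph::make_empty_graph(3, directed = FALSE)), 0)
})

test_that("transitivity equals brute-force triple enumeration on random graphs", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(3:12, 1)
    adj <- random_graph_adj(n, stats::runif(1, 0.1, 0.9))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(global_transitivity(g), oracle_transitivity(adj), tolerance = 1e-12)
  }
})

test_that("edge sets and O/E values equal exhaustive contingency counting", {
  set.seed(17)
  kw_pool <- letters[1:8]
  for (rep in 1:30) {
    n_pub <- sample(5:30, 1)
    sets <- replicate(n_pub, {
      sample(kw_pool, sample(0:5, 1))
    }, simplify = FALSE)
    stats <- compute_cooccurrence(kwsets_corpus(sets), kw_pool)
    oracle <- oracle_cooccurrence(sets, kw_pool)
    expect_equal(unname(stats$n_i), unname(oracle$n_i))
    expect_equal(unname(stats$n_ij), unname(oracle$n_ij))
    expect_equal(unname(stats$O), unname(oracle$O))
    expect_equal(unname(stats$E), unname(oracle$E))
    # edge criterion and transitivity against the oracle adjacency
    net <- build_network(stats)
    adj_oracle <- (oracle$O > oracle$E) * 1
    g_oracle <- igraph::graph_from_adjacency_matrix(adj_oracle, mode = "undirected")
    expect_equal(
      igraph::ecount(net), igraph::ecount(g_oracle)
    )
    expect_equal(global_transitivity(net), oracle_transitivity(adj_oracle),
                 tolerance = 1e-12)
  }
})

test_that("observed-minus-expected excess shrinks with corpus size under independence", {
  # keywords sampled independently: no true structure
  mean_abs_excess <- vapply(c(50, 200, 800), function(N) {
    set.seed(23)
    sets <- replicate(N, letters[stats::runif(6) < 0.3], simplify = FALSE)
    stats <- compute_cooccurrence(kwsets_corpus(sets), letters[1:6])
    mean(abs(stats$O - stats$E)[upper.tri(stats$O)])
  }, numeric(1))
  expect_true(all(diff(mean_abs_excess) < 0))
})

test_that("bootstrap transitivity CIs are reproducible and cover the point estimate", {
  gen <- generate_corpus(small_synth(seed = 13, years = 1992:2001))
  norm <- normalize_corpus(gen$corpus, gen$synonyms)
  kws <- top_keywords(norm, 15, exclude = "api mellifera")
  t_hat <- global_transitivity(build_network(compute_cooccurrence(norm, kws)))
  ci <- suppressWarnings(
    bootstrap_transitivity_ci(norm, kws, n_boot = 200, level = 0.95, seed = 3)
  )
  expect_lte(ci$low, t_hat)
  expect_gte(ci$high, t_hat)
  ci2 <- suppressWarnings(
    bootstrap_transitivity_ci(norm, kws, n_boot = 200, level = 0.95, seed = 3)
  )
  expect_identical(ci[c("low", "high")], ci2[c("low", "high")])

  # corpus whose every resample yields the same triangle: half the
  # publications carry {a, b, c}, half carry an unrelated keyword, so
  # any mixed resample keeps O > E for the three pairs (a resample of
  # only one type is vanishingly rare at 20 publications)
  tri <- kwsets_corpus(c(
    replicate(10, c("a", "b", "c"), simplify = FALSE),
    replicate(10, "d", simplify = FALSE)
  ))
  ci_tri <- suppressWarnings(
    bootstrap_transitivity_ci(tri, c("a", "b", "c"), n_boot = 120, seed = 1)
  )
  expect_equal(c(ci_tri$low, ci_tri$high), c(1, 1))
})

test_that("network exports round-trip through GraphML and write valid GEXF/TSV", {
  sets <- c(
    replicate(4, c("a", "b", "c"), simplify = FALSE),
    replicate(2, c("a", "d"), simplify = FALSE),
    replicate(3, "e", simplify = FALSE)
  )
  corpus <- kwsets_corpus(sets)
  stats <- compute_cooccurrence(corpus, c("a", "b", "c", "d", "e"))
  net <- build_network(stats)

  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)

  gexf <- tempfile(fileext = ".gexf")
  write_gexf(net, gexf)
  doc <- xml2::read_xml(gexf)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")),
               igraph::vcount(net))
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")),
               igraph::ecount(net))

  tsv <- tempfile(fileext = ".tsv")
  write_edgelist_tsv(net, tsv, stats)
  tab <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(tab), igraph::ecount(net))
  expect_true(all(tab$weight > 0))
  expect_equal(tab$weight, tab$O - tab$E, tolerance = 1e-12)
})
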