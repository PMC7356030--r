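norm_of <- function(corpus, map = synonym_map()) normalize_corpus(corpus, map)

test_that("top keywords rank by publication count with exclusion after the cut", {
  corpus <- mini_corpus(
    rep(2000, 6),
    keywords = list(c("a", "b"), c("a", "b"), c("a", "c"), "a", "b", "c")
  )
  expect_equal(top_keywords(corpus, 2), c("a", "b"))
  # lexicographic tie-break: a and b tie at 2 in this smaller corpus
  tie <- mini_corpus(rep(2000, 2), keywords = list(c("a", "b"), c("b", "a")))
  expect_equal(top_keywords(tie, 1), "a")
  # exclusion removes after ranking, shrinking the list
  expect_equal(top_keywords(corpus, 2, exclude = "a"), "b")
})

test_that("period keyword lists union like the study's 49 + 49 -> 65", {
  pre <- sprintf("kw%02d", 1:49)
  post <- sprintf("kw%02d", 17:65)  # shares 33 with pre
  expect_length(union_keywords(pre, post), 65)
  expect_equal(union_keywords(pre, pre), sort(pre))
  expect_length(union_keywords(c("a", "b"), c("c", "d")), 4)
})

test_that("the keyword-year matrix holds counts and per-year relative frequencies", {
  corpus <- mini_corpus(
    rep(2000, 4),
    keywords = list("varroa", "varroa", "forag", "pollen")
  )
  mat <- build_matrix(norm_of(corpus), c("varroa", "absent"))
  expect_equal(mat$counts["varroa", "2000"], 2)
  expect_equal(mat$values["varroa", "2000"], 0.5)
  expect_true(all(mat$counts["absent", ] == 0))
  expect_true(all(mat$values >= 0 & mat$values <= 1))
})

test_that("ward.D clustering merges identical columns first and matches hand computation", {
  # two identical year profiles merge first, at height 0
  m2 <- list(
    values = cbind(`2000` = c(1, 0), `2001` = c(1, 0), `2002` = c(0, 1)),
    years = 2000:2002
  )
  class(m2) <- "keyword_year_matrix"
  cl2 <- ward_cluster_years(m2)
  expect_equal(cl2$tree$height[1], 0)
  expect_setequal(unlist(top_split(cl2)[["1"]]), c(2000, 2001))

  # 1-d points {0, 1, 10}: first merge is {0, 1} at distance 1
  m3 <- list(values = cbind(a = 0, b = 1, c = 10), years = 1:3)
  class(m3) <- "keyword_year_matrix"
  cl3 <- ward_cluster_years(m3)
  expect_equal(cl3$tree$height[1], 1)
  expect_equal(sort(cl3$tree$merge[1, ]), c(-2, -1))

  expect_error(ward_cluster_years(list(values = cbind(a = 1), years = 1)), "2 years")
})

test_that("ward.D merge heights equal a reference Lance-Williams agglomeration", {
  set.seed(99)
  for (rep in 1:5) {
    X <- matrix(stats::runif(36), 6, 6,
                dimnames = list(NULL, paste0("y", 1:6)))
    mat <- list(values = X, years = 1:6)
    class(mat) <- "keyword_year_matrix"
    cl <- ward_cluster_years(mat)
    expect_equal(sort(cl$tree$height), sort(oracle_ward_heights(X)),
                 tolerance = 1e-9)
    expect_true(all(diff(cl$tree$height) >= -1e-12))
  }
})

test_that("bootstrap stability is reproducible, perfect for one cluster, and high for separated blocks", {
  # two well-separated synthetic decade blocks
  vals <- cbind(
    matrix(rep(c(1, 0), 10), nrow = 2) + 0.01 * matrix(seq_len(20), 2),
    matrix(rep(c(0, 1), 10), nrow = 2) + 0.01 * matrix(seq_len(20), 2)
  )
  colnames(vals) <- 1981:2000
  mat <- list(values = vals / max(vals), years = 1981:2000)
  class(mat) <- "keyword_year_matrix"
  stab <- bootstrap_cluster_stability(mat, n_boot = 200, n_clusters = 2, seed = 5)
  expect_true(all(stab > 0.9))
  stab2 <- bootstrap_cluster_stability(mat, n_boot = 200, n_clusters = 2, seed = 5)
  expect_identical(stab, stab2)
  expect_equal(unname(bootstrap_cluster_stability(mat, 10, 1, seed = 1)), 1)
})

test_that("enrichment ratios come from marginal sums and conserve totals", {
  mk_mat <- function(counts, years) {
    vals <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
    m <- list(counts = counts, values = vals, years = years,
              keywords = rownames(counts))
    class(m) <- "keyword_year_matrix"
    m
  }
  counts <- matrix(c(2, 0, 0, 2), 2, 2,
                   dimnames = list(c("a", "b"), c("2000", "2001")))
  mat <- mk_mat(counts, 2000:2001)
  cl <- ward_cluster_years(mat)
  enr <- enrichment(mat, cl, n_clusters = 2, top_n = 1)
  expect_true(all(enr$expected == 1))
  expect_equal(enr$ratio, matrix(c(2, 0, 0, 2), 2, 2,
                                 dimnames = dimnames(counts)))
  expect_equal(sum(enr$expected), sum(counts))

  # uniform counts: independence, all ratios 1, scores ~ 1.001
  unif <- matrix(3, 4, 5, dimnames = list(letters[1:4], 2000:2004))
  mat_u <- mk_mat(unif, 2000:2004)
  enr_u <- enrichment(mat_u, ward_cluster_years(mat_u), n_clusters = 2, top_n = 2)
  expect_true(all(abs(enr_u$ratio - 1) < 1e-12))
  expect_true(all(abs(enr_u$scores - 1.001) < 1e-9))

  # conservation on random count matrices
  set.seed(12)
  for (rep in 1:20) {
    counts <- matrix(stats::rpois(30, 3), 5, 6,
                     dimnames = list(paste0("k", 1:5), 1990:1995))
    mat_r <- mk_mat(counts, 1990:1995)
    enr_r <- enrichment(mat_r, ward_cluster_years(mat_r), n_clusters = 2)
    expect_equal(sum(enr_r$expected), sum(counts), tolerance = 1e-9)
    expect_true(all(enr_r$ratio >= 0))
  }
})

test_that("a cluster's enrichment score is the geometric mean of shifted ratios", {
  # keyword with cell ratios {2, 8} across a two-year cluster; scores are
  # computed through the enrichment() path on a matrix engineered to give
  # those ratios for keyword "a" with both years in one cluster
  counts <- matrix(c(2, 3, 8, 2, 30, 55), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("1990", "1991")))
  vals <- sweep(counts, 2, colSums(counts), "/")
  mat <- list(counts = counts, values = vals, years = 1990:1991,
              keywords = rownames(counts))
  class(mat) <- "keyword_year_matrix"
  grand <- sum(counts)
  expected_a <- outer(rowSums(counts), colSums(counts))["a", ] / grand
  ratios_a <- counts["a", ] / expected_a
  cl <- ward_cluster_years(mat)
  enr <- enrichment(mat, cl, n_clusters = 1, top_n = 3)
  expect_equal(
    unname(enr$scores["a", "1"]),
    exp(mean(log(ratios_a + 0.001))),
    tolerance = 1e-12
  )
  # and the closed form for ratio pair {2, 8}
  expect_equal(exp(mean(log(c(2, 8) + 0.001))), sqrt(2.001 * 8.001),
               tolerance = 1e-12)
})

test_that("dendrogram Newick export is readable and complete", {
  gen <- generate_corpus(small_synth(seed = 8, years = 1990:1999))
  norm <- normalize_corpus(gen$corpus, gen$synonyms)
  mat <- build_matrix(norm, top_keywords(norm, 10, exclude = "api mellifera"))
  cl <- ward_cluster_years(mat)
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, as.character(1990:1999))
})
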