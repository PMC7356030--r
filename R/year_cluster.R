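#' Year clustering by keyword frequency profiles
#'
#' Years are clustered by the similarity of their keyword usage: each
#' year is a vector of relative keyword frequencies (proportion of that
#' year's publications containing each of the selected top keywords),
#' clustered agglomeratively with the classical `ward.D` convention.
#' Cluster stability is assessed by bootstrapping the years and
#' recording mean maximal Jaccard similarity; dominant keywords per
#' cluster are scored by observed/expected enrichment ratios built from
#' marginal sums.
#'
#' @name year_cluster
NULL

#' Most frequent keywords of a corpus
#'
#' Ranks normalized keywords by the number of publications containing
#' them (descending, ties broken lexicographically), takes the top `k`,
#' then removes any member of `exclude` (typically the stemmed search
#' term, which trivially tops the ranking). Removal happens after the
#' top-k cut, so excluding one keyword from a top-50 list leaves 49.
#'
#' @param corpus a normalized `bee_corpus`.
#' @param k number of top keywords before exclusion.
#' @param exclude keywords to drop from the ranked list.
#' @return character vector of at most `k` keywords.
#' @export
top_keywords <- function(corpus, k, exclude = character(0)) {
  stopifnot(k >= 1)
  kws <- unlist(corpus$records$keywords, use.names = FALSE)
  if (!length(kws)) return(character(0))
  counts <- table(kws)
  ord <- order(-as.numeric(counts), names(counts))
  ranked <- names(counts)[ord]
  top <- ranked[seq_len(min(k, length(ranked)))]
  setdiff_keep_order <- top[!top %in% exclude]
  setdiff_keep_order
}

#' Union of two period keyword lists
#'
#' @param pre_top,post_top character vectors.
#' @return sorted set union.
#' @export
union_keywords <- function(pre_top, post_top) {
  sort(unique(c(pre_top, post_top)))
}

#' Build the keyword-by-year frequency matrix
#'
#' @param corpus a normalized `bee_corpus`.
#' @param keywords character vector of normalized keywords (rows).
#' @return list of class `keyword_year_matrix` with `counts`
#'   (publications per keyword and year), `values` (relative
#'   frequencies: counts divided by the year's publication total),
#'   `keywords`, `years`, and `year_totals`.
#' @export
build_matrix <- function(corpus, keywords) {
  stopifnot(length(keywords) >= 1)
  years <- sort(unique(corpus$records$year))
  if (!length(years)) stop("corpus has no records")
  year_totals <- vapply(years, function(yr) sum(corpus$records$year == yr), numeric(1))
  if (any(year_totals == 0)) stop("year with zero publications in matrix")
  counts <- matrix(
    0, nrow = length(keywords), ncol = length(years),
    dimnames = list(keywords, years)
  )
  yr_index <- match(corpus$records$year, years)
  for (i in seq_len(nrow(corpus$records))) {
    hit <- intersect(corpus$records$keywords[[i]], keywords)
    if (length(hit)) {
      counts[hit, yr_index[i]] <- counts[hit, yr_index[i]] + 1
    }
  }
  values <- sweep(counts, 2, year_totals, "/")
  structure(
    list(
      counts = counts, values = values,
      keywords = keywords, years = years, year_totals = year_totals
    ),
    class = "keyword_year_matrix"
  )
}

#' Ward-cluster the years of a keyword-year matrix
#'
#' Agglomerative clustering of the year columns on Euclidean distances
#' between relative-frequency profiles, with the classical `ward.D`
#' Lance-Williams update applied to the distances as given (unsquared).
#' `ward.D2`, which squares distances internally, is available behind a
#' flag.
#'
#' @param matrix a `keyword_year_matrix`.
#' @param method `"ward.D"` (default) or `"ward.D2"`.
#' @return list of class `year_clustering`: the `hclust` tree, `years`,
#'   and `method`.
#' @export
ward_cluster_years <- function(matrix, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  if (length(matrix$years) < 2L) stop("need at least 2 years to cluster")
  d <- stats::dist(t(matrix$values))
  tree <- stats::hclust(d, method = method)
  structure(
    list(tree = tree, years = matrix$years, method = method),
    class = "year_clustering"
  )
}

#' Year labels at a k-cluster cut
#'
#' @param clustering a `year_clustering`.
#' @param n_clusters number of clusters.
#' @return named integer vector of cluster labels per year.
#' @export
cut_years <- function(clustering, n_clusters) {
  stats::cutree(clustering$tree, k = n_clusters)
}

#' The two year-sets of the dendrogram's top split
#'
#' @param clustering a `year_clustering`.
#' @return list of two integer vectors of years.
#' @export
top_split <- function(clustering) {
  labels <- cut_years(clustering, 2L)
  split(clustering$years, labels)
}

#' Bootstrap cluster stability (mean Jaccard)
#'
#' Resamples the year columns with replacement, re-clusters each
#' resample, and records for every original cluster the maximum Jaccard
#' similarity with any bootstrap cluster, computed over the distinct
#' years present in the resample. The mean over replicates is the
#' stability of that cluster (1 = perfectly recovered every time).
#'
#' @param matrix a `keyword_year_matrix`.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param n_clusters number of clusters at which to cut both the
#'   original and each bootstrap tree.
#' @param seed integer RNG seed.
#' @param method clustering method, as in [ward_cluster_years()].
#' @return named numeric vector: mean Jaccard stability per original
#'   cluster label.
#' @export
bootstrap_cluster_stability <- function(matrix, n_boot, n_clusters, seed = 1L,
                                        method = "ward.D") {
  stopifnot(n_boot >= 1)
  years <- matrix$years
  n <- length(years)
  if (n_clusters >= n) stop("n_clusters must be < number of years")
  orig <- cut_years(ward_cluster_years(matrix, method), n_clusters)
  orig_sets <- split(years, orig)
  if (n_clusters == 1L) {
    return(stats::setNames(1, names(orig_sets)))
  }
  set.seed(seed)
  sims <- base::matrix(NA_real_, nrow = n_boot, ncol = length(orig_sets))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    uniq <- sort(unique(idx))
    if (length(uniq) < 2L) {
      sims[b, ] <- NA_real_
      next
    }
    sub <- list(
      values = matrix$values[, uniq, drop = FALSE],
      years = years[uniq]
    )
    class(sub) <- "keyword_year_matrix"
    k_eff <- min(n_clusters, length(uniq))
    boot_lab <- stats::cutree(
      stats::hclust(stats::dist(t(sub$values)), method = method), k = k_eff
    )
    boot_sets <- split(sub$years, boot_lab)
    present <- years[uniq]
    for (ci in seq_along(orig_sets)) {
      a <- intersect(orig_sets[[ci]], present)
      if (!length(a)) {
        sims[b, ci] <- NA_real_
        next
      }
      sims[b, ci] <- max(vapply(boot_sets, function(bset) {
        length(intersect(a, bset)) / length(union(a, bset))
      }, numeric(1)))
    }
  }
  stats::setNames(colMeans(sims, na.rm = TRUE), names(orig_sets))
}

#' Observed/expected keyword enrichment by cluster
#'
#' On the raw counts matrix, the expected count of keyword i in year j
#' under independence of keyword and year is
#' `row_sum_i * col_sum_j / grand_total`; the cell ratio is
#' observed/expected (0 where the expectation is 0). Per cluster the
#' keyword's score is the geometric mean over the cluster's years of
#' (ratio + 0.001); the small shift keeps a single zero ratio from
#' annihilating the geometric mean while leaving nonzero ratios
#' essentially unchanged.
#'
#' @param matrix a `keyword_year_matrix`.
#' @param clustering a `year_clustering` over the same years.
#' @param n_clusters number of clusters to cut.
#' @param top_n keywords to report per cluster.
#' @return list of class `enrichment_table`: `expected` and `ratio`
#'   matrices, `scores` (keyword x cluster geometric-mean matrix), and
#'   `top` (tibble cluster/keyword/score/rank).
#' @export
enrichment <- function(matrix, clustering, n_clusters, top_n = 3L) {
  stopifnot(top_n >= 1)
  counts <- matrix$counts
  grand <- sum(counts)
  if (grand == 0) stop("counts matrix is all zero")
  expected <- outer(rowSums(counts), colSums(counts)) / grand
  ratio <- ifelse(expected > 0, counts / expected, 0)
  labels <- cut_years(clustering, n_clusters)
  clusters <- sort(unique(labels))
  scores <- vapply(clusters, function(cl) {
    cols <- which(labels == cl)
    exp(rowMeans(log(ratio[, cols, drop = FALSE] + 0.001)))
  }, numeric(nrow(counts)))
  scores <- base::matrix(scores, nrow = nrow(counts),
                         dimnames = list(rownames(counts), clusters))
  top <- dplyr::bind_rows(lapply(clusters, function(cl) {
    s <- scores[, as.character(cl)]
    ord <- order(-s, names(s))
    take <- ord[seq_len(min(top_n, length(ord)))]
    tibble::tibble(
      cluster = cl,
      keyword = names(s)[take],
      score = unname(s[take]),
      rank = seq_along(take)
    )
  }))
  structure(
    list(expected = expected, ratio = ratio, scores = scores, top = top),
    class = "enrichment_table"
  )
}

#' Export a year dendrogram as Newick text
#'
#' @param clustering a `year_clustering`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
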