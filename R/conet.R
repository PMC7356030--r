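#' Keyword co-occurrence networks under an independence null
#'
#' For a keyword pair (i, j), the observed co-occurrence probability O
#' is the fraction of publications containing both keywords; the
#' expected probability under independence is E = p(i) * p(j), the
#' product of the keywords' marginal publication probabilities. Pairs
#' with O strictly greater than E are connected by an edge of weight
#' O - E, so edge thickness reflects how much more often two keywords
#' travel together than chance predicts.
#'
#' @name conet
NULL

#' Pairwise co-occurrence statistics
#'
#' Counts are publication-level: a keyword counts once per publication
#' no matter how often it appears, and a pair counts once per
#' publication containing both. O is normalized by the number of
#' publications so that O and E are commensurable probabilities.
#'
#' @param corpus a normalized `bee_corpus`.
#' @param keywords keyword node set (normalized forms).
#' @return list of class `cooccurrence_stats`: `N`, per-keyword counts
#'   `n_i`, symmetric pair-count matrix `n_ij`, marginal probabilities
#'   `p_i`, and matrices `O` and `E` (diagonals set to 0).
#' @export
compute_cooccurrence <- function(corpus, keywords) {
  if (!length(keywords)) stop("keyword list must be non-empty")
  N <- nrow(corpus$records)
  if (N < 1L) stop("corpus must contain at least one publication")
  # publication x keyword incidence
  inc <- vapply(
    corpus$records$keywords,
    function(kws) keywords %in% kws,
    logical(length(keywords))
  )
  inc <- base::matrix(as.numeric(inc), nrow = length(keywords),
                      dimnames = list(keywords, NULL))
  n_i <- rowSums(inc)
  n_ij <- tcrossprod(inc)
  diag(n_ij) <- 0
  p_i <- n_i / N
  O <- n_ij / N
  E <- outer(p_i, p_i)
  diag(E) <- 0
  structure(
    list(N = N, n_i = n_i, n_ij = n_ij, p_i = p_i, O = O, E = E),
    class = "cooccurrence_stats"
  )
}

#' Build the keyword network from co-occurrence statistics
#'
#' Edge (i, j) is present iff `O_ij > E_ij` strictly, with weight
#' `O_ij - E_ij`. Isolated keywords stay in the node set.
#'
#' @param stats a `cooccurrence_stats`.
#' @return an undirected weighted `igraph` graph.
#' @export
build_network <- function(stats) {
  excess <- stats$O - stats$E
  adj <- ifelse(excess > 0, excess, 0)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(
    adj, mode = "undirected", weighted = TRUE, diag = FALSE
  )
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Global transitivity (clustering coefficient)
#'
#' 3 times the number of triangles divided by the number of connected
#' triplets (paths of length 2); 0 when the graph has no connected
#' triplet. Edge weights are ignored.
#'
#' @param net an undirected `igraph` graph.
#' @return value in [0, 1].
#' @export
global_transitivity <- function(net) {
  t <- igraph::transitivity(net, type = "global")
  if (is.nan(t)) 0 else t
}

#' Bootstrap confidence interval for network transitivity
#'
#' Resamples publications with replacement (the keyword node set stays
#' fixed), rebuilds the O > E network on each replicate, and returns a
#' percentile interval of the replicate transitivities.
#'
#' @param corpus a normalized `bee_corpus`.
#' @param keywords keyword node set.
#' @param n_boot bootstrap replicates; percentile intervals are
#'   unreliable below a few hundred (warning under 100).
#' @param level interval coverage, e.g. 0.95.
#' @param seed integer RNG seed.
#' @return list: `low`, `high`, `level`, `replicates` (numeric vector).
#' @export
bootstrap_transitivity_ci <- function(corpus, keywords, n_boot = 1000L,
                                      level = 0.95, seed = 1L) {
  if (n_boot < 100L) warning("percentile CIs are unreliable for n_boot < 100")
  N <- nrow(corpus$records)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(N, N, replace = TRUE)
    rec <- corpus$records[idx, ]
    rec$id <- sprintf("b%06d", seq_len(N))
    boot_corpus <- bee_corpus(rec, year_range = corpus$year_range)
    global_transitivity(build_network(compute_cooccurrence(boot_corpus, keywords)))
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(low = q[1], high = q[2], level = level, replicates = reps)
}

#' Export a network as an edge-list TSV
#'
#' Columns: source, target, weight (plus O and E when a
#' `cooccurrence_stats` is supplied).
#'
#' @param net an `igraph` graph with a `weight` edge attribute.
#' @param path output file.
#' @param stats optional `cooccurrence_stats` to annotate O and E.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(net, path, stats = NULL) {
  el <- igraph::as_edgelist(net)
  out <- tibble::tibble(
    source = el[, 1],
    target = el[, 2],
    weight = igraph::E(net)$weight %||% rep(1, nrow(el))
  )
  if (!is.null(stats)) {
    out$O <- stats$O[cbind(out$source, out$target)]
    out$E <- stats$E[cbind(out$source, out$target)]
    out <- out[, c("source", "target", "O", "E", "weight")]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' @param net an `igraph` graph.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Export a network as GEXF
#'
#' Minimal GEXF 1.2 writer (node list with a `degree` attribute, edge
#' list with weights), sufficient for import into Gephi-style tools.
#'
#' @param net an `igraph` graph.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(net, path) {
  xml_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(net)))
  deg <- igraph::degree(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight %||% rep(1, nrow(el))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gexf xmlns=\"http://www.gexf.net/1.2draft\" version=\"1.2\">",
    "  <graph mode=\"static\" defaultedgetype=\"undirected\">",
    "    <attributes class=\"node\">",
    "      <attribute id=\"0\" title=\"degree\" type=\"integer\"/>",
    "    </attributes>",
    "    <nodes>",
    sprintf(
      "      <node id=\"%d\" label=\"%s\"><attvalues><attvalue for=\"0\" value=\"%d\"/></attvalues></node>",
      seq_along(nodes) - 1L, xml_escape(nodes), deg
    ),
    "    </nodes>",
    "    <edges>",
    if (nrow(el)) sprintf(
      "      <edge id=\"%d\" source=\"%d\" target=\"%d\" weight=\"%.10g\"/>",
      seq_len(nrow(el)) - 1L, el[, 1] - 1L, el[, 2] - 1L, w
    ) else character(0),
    "    </edges>",
    "  </graph>",
    "</gexf>"
  )
  writeLines(lines, path)
  invisible(path)
}
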