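# Shared fixtures and independent oracles for the suite.

# small in-memory corpus from compact arguments
mini_corpus <- function(years, keywords = NULL, titles = NULL, abstracts = NULL) {
  n <- length(years)
  if (is.null(keywords)) keywords <- replicate(n, character(0), simplify = FALSE)
  tibble_rec <- tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    year = as.integer(years),
    title = titles %||% rep("", n),
    abstract = abstracts %||% rep("", n),
    keywords = keywords
  )
  bee_corpus(tibble_rec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scaled-down synthetic study conditions used across tests: same
# generative structure as the defaults, fewer years and publications
small_synth <- function(seed = 1L, years = 1985:2004, regime_year = NULL,
                        amplitude = 6, rate = 0.06, ...) {
  if (is.null(regime_year)) regime_year <- years[ceiling(length(years) / 2)]
  synth_config(
    years = years, amplitude = amplitude, rate = rate,
    regime_year = regime_year, seed = seed, ...
  )
}

# --- independent oracles ----------------------------------------------------

# transitivity by exhaustive triple enumeration on an adjacency matrix
oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0
  triplets <- 0
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      e <- adj[i, j] + adj[i, k] + adj[j, k]
      if (e == 3) {
        triangles <- triangles + 1
        triplets <- triplets + 3
      } else if (e == 2) {
        triplets <- triplets + 1
      }
    }
  }
  if (triplets == 0) 0 else 3 * triangles / triplets
}

# exhaustive publication-level contingency counting for a pair list
oracle_cooccurrence <- function(keyword_sets, keywords) {
  N <- length(keyword_sets)
  n_i <- vapply(keywords, function(k) {
    sum(vapply(keyword_sets, function(s) k %in% s, logical(1)))
  }, numeric(1))
  m <- length(keywords)
  n_ij <- matrix(0, m, m, dimnames = list(keywords, keywords))
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a == b) next
    n_ij[a, b] <- sum(vapply(
      keyword_sets,
      function(s) keywords[a] %in% s && keywords[b] %in% s,
      logical(1)
    ))
  }
  E <- outer(n_i / N, n_i / N)
  diag(E) <- 0
  list(N = N, n_i = n_i, n_ij = n_ij, O = n_ij / N, E = E)
}

# naive agglomerative clustering with the classical ward.D
# Lance-Williams update applied to unsquared Euclidean distances;
# returns merge heights in merge order
oracle_ward_heights <- function(X) {
  # X: observations in columns
  n <- ncol(X)
  D <- as.matrix(stats::dist(t(X)))
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    sub <- D[active, active, drop = FALSE]
    diag(sub) <- Inf
    ix <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[ix[1]]; j <- active[ix[2]]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    h <- D[i, j]
    heights <- c(heights, h)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      ai <- (ni + nk) / (ni + nj + nk)
      aj <- (nj + nk) / (ni + nj + nk)
      beta <- -nk / (ni + nj + nk)
      D[i, k] <- D[k, i] <- ai * D[i, k] + aj * D[j, k] + beta * h
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# random undirected graph as adjacency matrix
random_graph_adj <- function(n, p) {
  adj <- matrix(0, n, n)
  upper <- which(upper.tri(adj))
  on <- upper[stats::runif(length(upper)) < p]
  adj[on] <- 1
  adj + t(adj)
}
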