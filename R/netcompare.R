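#' Comparing topic-word networks with keyword networks
#'
#' The two network families name their nodes differently: keyword
#' networks carry multi-word stemmed keywords ("foraging behavior" ->
#' "forag behavior"), topic networks carry single stems ("forag").
#' Overlap is therefore assessed with exact matches plus contiguous
#' substring matches in either direction, with a minimum matched
#' length of three characters so short stems cannot match
#' promiscuously. Fractions are computed over the subject network
#' (conventionally the topic network), asking how much of it the
#' reference (keyword) network already covers.
#'
#' @name netcompare
NULL

node_names <- function(net) {
  nm <- igraph::V(net)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(net))) else nm
}

# exact / substring / none match between two node names
match_type <- function(a, b, min_sub = 3L) {
  if (a == b) return("exact")
  if (nchar(a) >= min_sub && grepl(a, b, fixed = TRUE)) return("substring")
  if (nchar(b) >= min_sub && grepl(b, a, fixed = TRUE)) return("substring")
  "none"
}

#' Node overlap between two networks
#'
#' A subject node is matched if some reference node equals it or
#' relates to it by contiguous substring (either direction, >= 3
#' matched characters). Each subject node is counted once, against its
#' first match in reference order.
#'
#' @param subject,reference `igraph` graphs with lowercase normalized
#'   node names.
#' @param min_sub minimum substring length (default 3).
#' @return list of class `overlap_report` element: `fraction`,
#'   `matches` (tibble subject/reference/type), `n_subject`.
#' @export
node_overlap <- function(subject, reference, min_sub = 3L) {
  subj <- node_names(subject)
  ref <- node_names(reference)
  if (!length(subj)) stop("subject network has no nodes; overlap undefined")
  rows <- lapply(subj, function(a) {
    for (b in ref) {
      mt <- match_type(a, b, min_sub)
      if (mt != "none") {
        return(tibble::tibble(subject = a, reference = b, type = mt))
      }
    }
    NULL
  })
  matches <- dplyr::bind_rows(rows)
  if (!nrow(matches)) {
    matches <- tibble::tibble(subject = character(0),
                              reference = character(0),
                              type = character(0))
  }
  list(
    fraction = nrow(matches) / length(subj),
    matches = matches,
    n_subject = length(subj)
  )
}

#' Edge overlap between two networks
#'
#' A subject edge \{a, b\} matches a reference edge \{c, d\} if the
#' unordered pair can be aligned endpoint-to-endpoint so that each
#' endpoint matches exactly or by substring. Match cases: (1) both
#' endpoints exact, (2) one exact and one substring, (3) both
#' substring. Greedy first-match: each subject edge is counted once
#' against the first reference edge that accepts it.
#'
#' @inheritParams node_overlap
#' @return list: `fraction`, `matches` (tibble with subject/reference
#'   endpoints and `case` 1-3), `n_subject` (subject edge count).
#' @export
edge_overlap <- function(subject, reference, min_sub = 3L) {
  subj_el <- igraph::as_edgelist(subject)
  ref_el <- igraph::as_edgelist(reference)
  if (!nrow(subj_el)) stop("subject network has no edges; overlap undefined")
  case_of <- function(t1, t2) {
    n_exact <- sum(c(t1, t2) == "exact")
    c(3L, 2L, 1L)[n_exact + 1L]
  }
  rows <- lapply(seq_len(nrow(subj_el)), function(i) {
    a <- subj_el[i, 1]; b <- subj_el[i, 2]
    for (j in seq_len(nrow(ref_el))) {
      c_ <- ref_el[j, 1]; d_ <- ref_el[j, 2]
      # alignment 1: a~c, b~d
      t1 <- match_type(a, c_, min_sub); t2 <- match_type(b, d_, min_sub)
      if (t1 != "none" && t2 != "none") {
        return(tibble::tibble(subject_a = a, subject_b = b,
                              reference_a = c_, reference_b = d_,
                              case = case_of(t1, t2)))
      }
      # alignment 2: a~d, b~c
      t1 <- match_type(a, d_, min_sub); t2 <- match_type(b, c_, min_sub)
      if (t1 != "none" && t2 != "none") {
        return(tibble::tibble(subject_a = a, subject_b = b,
                              reference_a = d_, reference_b = c_,
                              case = case_of(t1, t2)))
      }
    }
    NULL
  })
  matches <- dplyr::bind_rows(rows)
  if (!nrow(matches)) {
    matches <- tibble::tibble(
      subject_a = character(0), subject_b = character(0),
      reference_a = character(0), reference_b = character(0),
      case = integer(0)
    )
  }
  list(
    fraction = nrow(matches) / nrow(subj_el),
    matches = matches,
    n_subject = nrow(subj_el)
  )
}

#' Full overlap report between a topic network and a keyword network
#'
#' @inheritParams node_overlap
#' @return list of class `overlap_report` with `nodes` and `edges`
#'   (each as returned by the respective function).
#' @export
overlap_report <- function(subject, reference, min_sub = 3L) {
  structure(
    list(
      nodes = node_overlap(subject, reference, min_sub),
      edges = edge_overlap(subject, reference, min_sub)
    ),
    class = "overlap_report"
  )
}

#' Write an overlap report as JSON and a match TSV
#'
#' @param report an `overlap_report`.
#' @param path_json,path_tsv optional output paths.
#' @return the report, invisibly.
#' @export
write_overlap_report <- function(report, path_json = NULL, path_tsv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(
        node_overlap_fraction = report$nodes$fraction,
        edge_overlap_fraction = report$edges$fraction,
        n_subject_nodes = report$nodes$n_subject,
        n_subject_edges = report$edges$n_subject
      ),
      path_json, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(path_tsv)) {
    node_df <- report$nodes$matches
    node_df$kind <- if (nrow(node_df)) "node" else character(0)
    edge_df <- report$edges$matches
    edge_df$kind <- if (nrow(edge_df)) "edge" else character(0)
    readr::write_tsv(dplyr::bind_rows(node_df, edge_df), path_tsv, progress = FALSE)
  }
  invisible(report)
}
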