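#' Keyword normalization: synonym mapping and stemming
#'
#' Author-assigned keywords are free text, so one concept surfaces under
#' many lexical variants ("honey-bee apis mellifera", "honey bee
#' a. mellifera", ...). Normalization first maps variants to a canonical
#' form via a manually curated synonym table, then collapses inflection
#' by Porter stemming each token, and finally deduplicates within each
#' record. The synonym table is written against surface forms, which is
#' why synonymization precedes stemming.
#'
#' @name normalize
NULL

#' Build a synonym map
#'
#' @param variants character vector of variant keywords.
#' @param canonical character vector of canonical forms, same length.
#' @return a named character vector (lowercased variant -> canonical)
#'   of class `synonym_map`. Idempotence is enforced: no canonical form
#'   may itself appear as a variant key mapping elsewhere.
#' @export
synonym_map <- function(variants = character(0), canonical = character(0)) {
  stopifnot(length(variants) == length(canonical))
  variants <- tolower(trimws(variants))
  canonical <- tolower(trimws(canonical))
  if (any(!nzchar(variants)) || any(!nzchar(canonical))) {
    stop("synonym map entries must be non-empty")
  }
  # self-maps are harmless but redundant
  keep <- variants != canonical
  variants <- variants[keep]
  canonical <- canonical[keep]
  if (anyDuplicated(variants)) stop("duplicate variant keys in synonym map")
  bad <- intersect(variants, canonical)
  if (length(bad)) {
    stop(
      "synonym map is not idempotent; canonical form(s) also appear as variants: ",
      paste(bad, collapse = ", ")
    )
  }
  structure(stats::setNames(canonical, variants), class = "synonym_map")
}

#' Read a synonym map from a two-column TSV
#'
#' Format: `variant TAB canonical`, UTF-8, `#` comment lines allowed.
#'
#' @param path file path.
#' @return a [synonym_map()].
#' @export
read_synonym_map <- function(path) {
  if (!file.exists(path)) stop("cannot read synonym map: ", path)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(synonym_map())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed synonym map line(s): ", which(bad)[1])
  synonym_map(
    variants = vapply(parts, `[`, character(1), 1L),
    canonical = vapply(parts, `[`, character(1), 2L)
  )
}

#' Write a synonym map to TSV
#' @param map a [synonym_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synonym_map <- function(map, path) {
  readr::write_lines(paste(names(map), unname(unclass(map)), sep = "\t"), path)
  invisible(path)
}

#' Keywords occurring more than once across a corpus
#'
#' The manual synonym-curation effort is scoped to keywords that recur:
#' a keyword used in a single publication cannot create a redundancy.
#'
#' @param corpus a `bee_corpus`.
#' @return character vector of lowercased keywords with total
#'   occurrence count > 1, sorted.
#' @export
repeated_keywords <- function(corpus) {
  kws <- tolower(unlist(corpus$records$keywords, use.names = FALSE))
  if (!length(kws)) return(character(0))
  counts <- table(kws)
  sort(names(counts)[counts > 1L])
}

#' Apply a synonym map to keywords
#'
#' Lowercases each keyword and replaces it by its canonical form when a
#' map entry exists; unmapped keywords pass through unchanged. Matching
#' is case-insensitive exact-string. Order is preserved and the
#' operation is idempotent.
#'
#' @param keywords character vector.
#' @param map a [synonym_map()].
#' @return character vector, same length.
#' @export
apply_synonyms <- function(keywords, map) {
  keywords <- tolower(trimws(keywords))
  hit <- match(keywords, names(map))
  found <- !is.na(hit)
  keywords[found] <- unname(unclass(map))[hit[found]]
  keywords
}

#' Stem a multi-word keyword
#'
#' Lowercases, tokenizes on whitespace, Porter-stems each token, and
#' rejoins with single spaces. Stop-tokens inside keywords (e.g. the
#' "of" in "division of labor") are preserved so keywords stay
#' recognizable in reports.
#'
#' @param term non-empty keyword (may contain spaces).
#' @return stemmed keyword.
#' @export
stem_keyword <- function(term) {
  if (length(term) != 1L || is.na(term) || !nzchar(trimws(term))) {
    stop("stem_keyword requires a single non-empty keyword")
  }
  toks <- strsplit(tolower(trimws(term)), "\\s+")[[1]]
  paste(porter_stem(toks), collapse = " ")
}

stem_keywords <- function(terms) {
  if (!length(terms)) return(character(0))
  vapply(terms, stem_keyword, character(1), USE.NAMES = FALSE)
}

#' Normalize all keywords in a corpus
#'
#' Per record: lowercase, apply the synonym map, Porter-stem each
#' keyword token-wise, then deduplicate with set semantics (first
#' occurrence kept). Record order is unchanged. The result is marked
#' with class `bee_corpus_normalized`.
#'
#' @param corpus a `bee_corpus`.
#' @param map a [synonym_map()] (empty map allowed).
#' @return the corpus with normalized keyword sets.
#' @export
normalize_corpus <- function(corpus, map = synonym_map()) {
  records <- corpus$records
  canon <- lapply(records$keywords, function(kws) {
    if (!length(kws)) character(0) else apply_synonyms(kws, map)
  })
  # stem each distinct surface form once across the whole corpus
  uniq <- unique(unlist(canon, use.names = FALSE))
  stemmed <- stats::setNames(stem_keywords(uniq), uniq)
  records$keywords <- lapply(canon, function(kws) {
    if (!length(kws)) character(0) else unique(unname(stemmed[kws]))
  })
  out <- bee_corpus(records, year_range = corpus$year_range)
  class(out) <- c("bee_corpus_normalized", class(out))
  out
}
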