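#' Bibliographic corpus container
#'
#' A `bee_corpus` wraps a tibble of publication records (one row per
#' publication: `id`, `year`, `title`, `abstract`, and a list-column
#' `keywords` of author-assigned keywords) together with the inclusive
#' year range the corpus covers.
#'
#' @param records tibble with columns `id`, `year`, `title`, `abstract`,
#'   `keywords` (list of character vectors).
#' @param year_range optional length-2 integer vector; defaults to the
#'   min/max year present in `records`.
#' @return an object of class `bee_corpus`.
#' @export
bee_corpus <- function(records, year_range = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("id", "year", "title", "abstract", "keywords")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- tibble::as_tibble(records)[needed]
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  if (nrow(records) && any(!is.finite(records$year))) {
    stop("all records must carry a finite year")
  }
  if (is.null(year_range)) {
    year_range <- if (nrow(records)) range(records$year) else c(NA_integer_, NA_integer_)
  }
  structure(
    list(records = records, year_range = as.integer(year_range)),
    class = "bee_corpus"
  )
}

#' @export
print.bee_corpus <- function(x, ...) {
  cat(sprintf(
    "<bee_corpus> %d publications, years %s-%s\n",
    nrow(x$records), x$year_range[1], x$year_range[2]
  ))
  invisible(x)
}

#' Number of publications in a corpus
#' @param corpus a `bee_corpus`.
#' @return integer count of records.
#' @export
n_publications <- function(corpus) nrow(corpus$records)

scopus_default_columns <- list(
  title = "Title",
  year = "Year",
  abstract = "Abstract",
  keywords = "Author Keywords"
)

#' Read a Scopus-style CSV export
#'
#' Parses one publication per data row. The keyword cell is split on the
#' Scopus `"; "` delimiter (a bare `";"` with surrounding whitespace is
#' also accepted, since real exports vary) and each token is trimmed.
#' Missing abstract or keyword cells yield empty values. Rows whose year
#' does not parse as an integer are skipped and counted in the load
#' report attached as attribute `"load_report"` (rows read / parsed /
#' skipped), which is also emitted as a message.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param dialect export dialect; only `"scopus-csv"` is supported.
#' @param columns named list overriding the default column names
#'   (`Title`, `Year`, `Abstract`, `Author Keywords`).
#' @return a [bee_corpus()].
#' @export
read_publications <- function(path, dialect = "scopus-csv",
                              columns = scopus_default_columns) {
  if (!identical(dialect, "scopus-csv")) {
    stop("unsupported dialect: ", dialect)
  }
  if (!file.exists(path)) stop("cannot read file: ", path)
  columns <- utils::modifyList(scopus_default_columns, as.list(columns))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  for (col in c(columns$title, columns$year)) {
    if (!col %in% names(raw)) stop("required column absent from export: '", col, "'")
  }
  get_col <- function(name) {
    if (name %in% names(raw)) raw[[name]] else rep(NA_character_, nrow(raw))
  }
  year_raw <- get_col(columns$year)
  year <- suppressWarnings(as.integer(year_raw))
  ok <- !is.na(year) & year >= 1000L & year <= 9999L
  n_read <- nrow(raw)
  n_skipped <- sum(!ok)

  records <- tibble::tibble(
    id = sprintf("pub%06d", which(ok)),
    year = year[ok],
    title = dplyr::coalesce(get_col(columns$title)[ok], ""),
    abstract = dplyr::coalesce(get_col(columns$abstract)[ok], ""),
    keywords = parse_keyword_cells(get_col(columns$keywords)[ok])
  )
  corpus <- bee_corpus(records)
  report <- list(rows_read = n_read, rows_parsed = sum(ok), rows_skipped = n_skipped)
  attr(corpus, "load_report") <- report
  message(sprintf(
    "read_publications: %d rows read, %d parsed, %d skipped (unparseable year)",
    report$rows_read, report$rows_parsed, report$rows_skipped
  ))
  corpus
}

parse_keyword_cells <- function(cells) {
  lapply(cells, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
    toks <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
    toks[nzchar(toks)]
  })
}

#' Write a corpus back to the Scopus CSV dialect
#'
#' Inverse of [read_publications()] up to record ids: re-reading the
#' written file yields field-identical records.
#'
#' @param corpus a `bee_corpus`.
#' @param path output file path.
#' @param columns column-name overrides as in [read_publications()].
#' @return `path`, invisibly.
#' @export
write_publications <- function(corpus, path, columns = scopus_default_columns) {
  columns <- utils::modifyList(scopus_default_columns, as.list(columns))
  out <- tibble::tibble(
    !!columns$title := corpus$records$title,
    !!columns$year := as.character(corpus$records$year),
    !!columns$abstract := corpus$records$abstract,
    !!columns$keywords := vapply(
      corpus$records$keywords, paste, character(1), collapse = "; "
    )
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Drop years with too few publications
#'
#' Retains only records whose publication year reaches a minimum number
#' of publications, mirroring the inclusion threshold used when a
#' bibliographic query tail contains sparsely indexed years. Retained
#' years need not be contiguous; the corpus year range is recomputed
#' from what remains.
#'
#' @param corpus a `bee_corpus`.
#' @param min_count minimum publications per retained year (>= 1).
#' @return filtered `bee_corpus`.
#' @export
filter_years_by_min_count <- function(corpus, min_count) {
  stopifnot(min_count >= 1)
  if (!nrow(corpus$records)) return(corpus)
  counts <- table(corpus$records$year)
  keep_years <- as.integer(names(counts)[counts >= min_count])
  records <- corpus$records[corpus$records$year %in% keep_years, ]
  if (!nrow(records)) {
    return(bee_corpus(records, year_range = c(NA_integer_, NA_integer_)))
  }
  bee_corpus(records)
}

#' Split a corpus at a boundary year
#'
#' @param corpus a `bee_corpus`.
#' @param boundary_year first year of the later period.
#' @return list with elements `pre` (years < boundary) and `post`
#'   (years >= boundary); every record lands in exactly one side.
#' @export
split_by_period <- function(corpus, boundary_year) {
  pre_rec <- corpus$records[corpus$records$year < boundary_year, ]
  post_rec <- corpus$records[corpus$records$year >= boundary_year, ]
  mk <- function(rec) {
    if (nrow(rec)) bee_corpus(rec) else bee_corpus(rec, c(NA_integer_, NA_integer_))
  }
  list(pre = mk(pre_rec), post = mk(post_rec))
}
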