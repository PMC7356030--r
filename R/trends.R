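#' Temporal publication trends
#'
#' Annual publication counts, log-linear exponential growth fits with
#' doubling times, and per-keyword prevalence series.
#'
#' @name trends
NULL

#' Annual publication counts
#'
#' @param corpus a `bee_corpus`.
#' @return named numeric vector: count per year (years with zero
#'   records are omitted), names sorted ascending.
#' @export
annual_counts <- function(corpus) {
  if (!nrow(corpus$records)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(corpus$records$year)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Fit exponential publication growth
#'
#' Fits `y = a * exp(b * x)` with `x = year - x_origin` by ordinary
#' least squares of `ln(count)` on `x`; this matches how growth rates
#' and their R-squared are conventionally reported for publication
#' counts, and is deterministic. Zero-count years cannot enter a log
#' fit and are dropped with a warning. The doubling time is
#' `ln(2) / b` (infinite for a flat series).
#'
#' @param series named numeric vector (names = years) as returned by
#'   [annual_counts()].
#' @param x_origin year mapped to x = 0; defaults to the first fitted
#'   year. The doubling time and rate are origin-invariant.
#' @return list of class `growth_fit`: `a`, `b`, `r_squared`, `n`,
#'   `doubling_time`, `x_origin`, and the underlying `lm` fit.
#' @export
fit_exponential <- function(series, x_origin = NULL) {
  years <- as.numeric(names(series))
  y <- as.numeric(series)
  pos <- is.finite(y) & y > 0
  if (any(!pos)) {
    warning(sprintf("dropping %d non-positive year(s) from the log-linear fit", sum(!pos)))
  }
  years <- years[pos]
  y <- y[pos]
  if (length(y) < 3L) stop("need at least 3 positive-count years to fit growth")
  if (is.null(x_origin)) x_origin <- min(years)
  x <- years - x_origin
  fit <- stats::lm(log(y) ~ x)
  b <- unname(stats::coef(fit)[2])
  # a flat series should report a zero rate, not floating-point dust
  if (abs(b) < 1e-12) b <- 0
  r2 <- suppressWarnings(summary(fit)$r.squared)
  # an essentially perfect (including flat) fit has no residual scatter
  if (!is.finite(r2) || b == 0) r2 <- 1
  structure(
    list(
      a = exp(unname(stats::coef(fit)[1])),
      b = b,
      r_squared = r2,
      n = length(y),
      doubling_time = doubling_time(b),
      x_origin = x_origin,
      lm = fit
    ),
    class = "growth_fit"
  )
}

#' Doubling time of an exponential growth rate
#'
#' @param b growth rate per year.
#' @return `ln(2) / b` years; `Inf` when `b` is 0.
#' @export
doubling_time <- function(b) {
  if (b == 0) return(Inf)
  log(2) / b
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> y = %.3f * exp(%.4f x), R^2 = %.3f, n = %d, doubling time %.2f yr\n",
    x$a, x$b, x$r_squared, x$n, x$doubling_time
  ))
  invisible(x)
}

#' Per-keyword annual prevalence
#'
#' Proportion of each year's publications whose (normalized) keyword
#' set contains the keyword.
#'
#' @param corpus a normalized `bee_corpus`.
#' @param keyword a single keyword, already in normalized form.
#' @return named numeric vector over the corpus's years, values in
#'   [0, 1].
#' @export
keyword_proportion_series <- function(corpus, keyword) {
  stopifnot(length(keyword) == 1L)
  if (!nrow(corpus$records)) return(stats::setNames(numeric(0), character(0)))
  years <- sort(unique(corpus$records$year))
  has_kw <- vapply(corpus$records$keywords, function(k) keyword %in% k, logical(1))
  prop <- vapply(years, function(yr) {
    in_year <- corpus$records$year == yr
    sum(has_kw & in_year) / sum(in_year)
  }, numeric(1))
  stats::setNames(prop, years)
}
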