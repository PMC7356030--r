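#' Porter stemming
#'
#' Rule-based suffix stripping following the classic Porter (1980)
#' algorithm: five ordered rule groups driven by the word's
#' consonant-vowel "measure". Keyword normalization and document
#' tokenization both run through this stemmer, so "foraging" and
#' "forage" collapse to "forag", and "colony" / "colonies" to "coloni".
#'
#' @param words character vector of lowercase (or mixed-case) words;
#'   each word is stemmed independently. Non-alphabetic characters are
#'   left untouched by the rules (the algorithm only inspects letters),
#'   so callers should tokenize first.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("foraging", "colonies", "pollination"))
#' @export
porter_stem <- function(words) {
  words <- tolower(words)
  uw <- unique(words)
  stems <- vapply(uw, porter_stem_one, character(1), USE.NAMES = FALSE)
  stems[match(words, uw)]
}

# --- single-word engine -----------------------------------------------------

# consonant test at position i (1-based); 'y' is a consonant unless it
# follows a consonant
.p_is_cons <- function(ch, i) {
  c_i <- ch[i]
  if (c_i %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c_i == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_is_cons(ch, i - 1L))
  }
  TRUE
}

.p_flags <- function(word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 0L) return(logical(0))
  vapply(seq_len(n), function(i) .p_is_cons(ch, i), logical(1))
}

# measure m of a stem: number of VC blocks in [C](VC)^m[V]
.p_measure <- function(word) {
  cons <- .p_flags(word)
  if (length(cons) == 0L) return(0L)
  rle_c <- rle(cons)
  # count transitions vowel-block -> consonant-block after the first block
  blocks <- rle_c$values
  m <- 0L
  for (i in seq_along(blocks)[-1]) {
    if (blocks[i] && !blocks[i - 1L]) m <- m + 1L
  }
  m
}

.p_has_vowel <- function(word) {
  any(!.p_flags(word))
}

.p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  cons <- .p_flags(word)
  cons[n]
}

# *o condition: stem ends cvc where the final consonant is not w, x or y
.p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cons <- .p_flags(word)
  if (!(cons[n] && !cons[n - 1L] && cons[n - 2L])) return(FALSE)
  !(substr(word, n, n) %in% c("w", "x", "y"))
}

.p_ends <- function(word, suffix) {
  n <- nchar(word)
  s <- nchar(suffix)
  n > s && substr(word, n - s + 1L, n) == suffix
}

.p_chop <- function(word, suffix) {
  substr(word, 1L, nchar(word) - nchar(suffix))
}

porter_stem_one <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # Step 1a
  if (.p_ends(word, "sses")) {
    word <- paste0(.p_chop(word, "sses"), "ss")
  } else if (.p_ends(word, "ies")) {
    word <- paste0(.p_chop(word, "ies"), "i")
  } else if (!.p_ends(word, "ss") && .p_ends(word, "s")) {
    word <- .p_chop(word, "s")
  }

  # Step 1b
  if (.p_ends(word, "eed")) {
    stem <- .p_chop(word, "eed")
    if (.p_measure(stem) > 0L) word <- paste0(stem, "ee")
  } else {
    removed <- FALSE
    if (.p_ends(word, "ed")) {
      stem <- .p_chop(word, "ed")
      if (.p_has_vowel(stem)) {
        word <- stem
        removed <- TRUE
      }
    } else if (.p_ends(word, "ing")) {
      stem <- .p_chop(word, "ing")
      if (.p_has_vowel(stem)) {
        word <- stem
        removed <- TRUE
      }
    }
    if (removed) {
      if (.p_ends(word, "at") || .p_ends(word, "bl") || .p_ends(word, "iz")) {
        word <- paste0(word, "e")
      } else if (.p_double_cons(word) &&
                 !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z"))) {
        word <- substr(word, 1L, nchar(word) - 1L)
      } else if (.p_measure(word) == 1L && .p_cvc(word)) {
        word <- paste0(word, "e")
      }
    }
  }

  # Step 1c
  if (.p_ends(word, "y") && .p_has_vowel(.p_chop(word, "y"))) {
    word <- paste0(.p_chop(word, "y"), "i")
  }

  # Step 2 (condition m(stem) > 0)
  step2 <- c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  )
  word <- .p_rule_table(word, step2, min_m = 1L)

  # Step 3 (condition m(stem) > 0)
  step3 <- c(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  )
  word <- .p_rule_table(word, step3, min_m = 1L)

  # Step 4 (condition m(stem) > 1); "ion" additionally requires the stem
  # to end in s or t
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  # longest suffix first within the step
  step4 <- step4[order(nchar(step4), decreasing = TRUE)]
  for (suf in step4) {
    if (.p_ends(word, suf)) {
      stem <- .p_chop(word, suf)
      ok <- .p_measure(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) word <- stem
      break
    }
  }

  # Step 5a
  if (.p_ends(word, "e")) {
    stem <- .p_chop(word, "e")
    m <- .p_measure(stem)
    if (m > 1L || (m == 1L && !.p_cvc(stem))) word <- stem
  }

  # Step 5b
  if (.p_measure(word) > 1L && .p_double_cons(word) &&
      substr(word, nchar(word), nchar(word)) == "l") {
    word <- substr(word, 1L, nchar(word) - 1L)
  }

  word
}

# apply the longest matching suffix rule from a named table, guarded by
# the measure of the candidate stem
.p_rule_table <- function(word, table, min_m) {
  sufs <- names(table)
  sufs <- sufs[order(nchar(sufs), decreasing = TRUE)]
  for (suf in sufs) {
    if (.p_ends(word, suf)) {
      stem <- .p_chop(word, suf)
      if (.p_measure(stem) >= min_m) word <- paste0(stem, table[[suf]])
      break
    }
  }
  word
}
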