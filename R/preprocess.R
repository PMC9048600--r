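#' Default English stop-word list
#'
#' A fixed, versioned stop-word list shipped with the package (rather than
#' taken from an external library) so that tokenization never drifts between
#' releases of a third-party resource.
#'
#' @return character vector of lowercase stop-words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "acealign")
  readLines(path, warn = FALSE)
}

#' Normalize an entity label into a token set
#'
#' Implements the label preprocessing pipeline used before similarity scoring:
#' digits and punctuation are stripped, the label is split on whitespace and
#' lowercase-to-uppercase boundaries (so `leafAlternatePlacement` becomes three
#' tokens while `Inflorescenceless` stays one), tokens are lowercased,
#' stop-words removed, the survivors stemmed, and finally the set is
#' deduplicated: a token literally equal or thesaurus-synonymous to an earlier
#' token in the same set is dropped. The result may be empty (e.g. for a label
#' consisting only of digits).
#'
#' @param raw label string (may be empty).
#' @param stop_words character vector of stop-words; defaults to the bundled
#'   list.
#' @param thesaurus a [thesaurus()] used for within-set synonym deduplication;
#'   defaults to the empty thesaurus (literal deduplication only).
#' @return object of class `token_set`: list with `words` (character vector of
#'   unique stems, in first-appearance order) and `source` (the raw label).
#' @export
#' @examples
#' preprocess_name("Plant trait 2")$words
preprocess_name <- function(raw, stop_words = default_stopwords(),
                            thesaurus = acealign::thesaurus()) {
  stopifnot(is.character(raw), length(raw) == 1L)
  x <- raw
  # camel-case boundaries become spaces before anything is lowercased
  x <- gsub("([a-z])([A-Z])", "\\1 \\2", x)
  x <- gsub("([A-Za-z])([0-9])", "\\1 \\2", x)
  # digits and punctuation (incl. underscores/hyphens) become separators
  x <- gsub("[^A-Za-z]+", " ", x)
  x <- tolower(trimws(x))
  words <- strsplit(x, "\\s+")[[1]]
  words <- words[nzchar(words)]
  words <- words[!(words %in% stop_words)]
  words <- porter_stem(words)
  # within-set deduplication: drop a word equal or synonymous to an earlier one
  kept <- character(0)
  for (w in words) {
    dup <- any(vapply(kept, function(k) are_synonyms(thesaurus, w, k),
                      logical(1)))
    if (!dup) kept <- c(kept, w)
  }
  structure(list(words = kept, source = raw), class = "token_set")
}

#' @export
print.token_set <- function(x, ...) {
  cat(sprintf("<token_set {%s} from %s>\n",
              paste(x$words, collapse = ", "), deparse(x$source)))
  invisible(x)
}
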