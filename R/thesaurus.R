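#' Synonym thesaurus
#'
#' A thesaurus is a symmetric, reflexive synonym oracle over normalized words.
#' It backs the first branch of the word similarity measure: a pair of words
#' recorded as synonyms scores 1 regardless of surface spelling. Adapters exist
#' for a plain tabular file (one `word1,word2` pair per line) and for an empty
#' thesaurus (pure n-gram matching). Entries are normalized with the same
#' stemmer as label tokens so that lookups happen in stem space.
#'
#' @param pairs data frame (or matrix) with two character columns of synonym
#'   word pairs. May have zero rows.
#' @param stem if `TRUE` (default), entries are stemmed on load with
#'   [porter_stem()] to match preprocessed tokens.
#' @return an object of class `thesaurus`.
#' @export
#' @examples
#' th <- thesaurus(data.frame(w1 = "movement", w2 = "drift"))
#' are_synonyms(th, porter_stem("movement"), porter_stem("drift"))
thesaurus <- function(pairs = NULL, stem = TRUE) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    keys <- character(0)
  } else {
    w1 <- tolower(trimws(as.character(pairs[[1]])))
    w2 <- tolower(trimws(as.character(pairs[[2]])))
    if (stem) {
      w1 <- porter_stem(w1)
      w2 <- porter_stem(w2)
    }
    keep <- nzchar(w1) & nzchar(w2)
    w1 <- w1[keep]
    w2 <- w2[keep]
    # store both orientations so lookup is symmetric
    keys <- unique(c(paste(w1, w2, sep = "\r"), paste(w2, w1, sep = "\r")))
  }
  structure(list(keys = keys), class = "thesaurus")
}

#' @export
print.thesaurus <- function(x, ...) {
  cat(sprintf("<thesaurus: %d synonym pair(s)>\n", length(x$keys) %/% 2L))
  invisible(x)
}

#' Read a thesaurus from a tabular file
#'
#' The file holds one synonym pair per line, `word1,word2`, with an optional
#' header. Lines starting with `#` are ignored.
#'
#' @param path path to the CSV file.
#' @inheritParams thesaurus
#' @return a `thesaurus` object.
#' @export
read_thesaurus <- function(path, stem = TRUE) {
  if (!file.exists(path)) stop("thesaurus file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) && grepl("^word1\\s*,", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (!length(lines)) return(thesaurus())
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) {
    stop("malformed thesaurus line: ", lines[which(bad)[1]], call. = FALSE)
  }
  thesaurus(
    data.frame(
      w1 = vapply(parts, `[[`, character(1), 1L),
      w2 = vapply(parts, `[[`, character(1), 2L)
    ),
    stem = stem
  )
}

#' The bundled fixture thesaurus
#'
#' A small static synonym table shipped with the package. It contains the
#' synonym pairs used by the synthetic benchmark generator plus a few
#' ecology/biodiversity pairs (e.g. movement/drift), so tests and examples run
#' without any external lexical resource.
#'
#' @return a `thesaurus` object.
#' @export
fixture_thesaurus <- function() {
  read_thesaurus(
    system.file("extdata", "fixture_thesaurus.csv", package = "acealign")
  )
}

#' Are two words synonyms?
#'
#' Reflexive, symmetric membership test: literal equality always counts as
#' synonymy, otherwise the thesaurus table is consulted.
#'
#' @param t a `thesaurus`.
#' @param w1,w2 single words (already normalized/stemmed).
#' @return logical scalar.
#' @export
are_synonyms <- function(t, w1, w2) {
  stopifnot(inherits(t, "thesaurus"))
  if (identical(w1, w2)) return(TRUE)
  paste(w1, w2, sep = "\r") %in% t$keys
}
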