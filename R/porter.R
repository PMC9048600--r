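# Porter's suffix-stripping stemmer (the classic 1980 algorithm), implemented
# directly so the token normalization pipeline is fixed and versioned with the
# package rather than drifting with an external stemming library.

porter_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(chars, i - 1L))
  }
  TRUE
}

# measure m of the stem: number of VC blocks in [C](VC)^m[V]
porter_measure <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) porter_is_cons(chars, i), logical(1))
  # collapse runs: sequence of C/V symbols
  runs <- rle(types)$values
  # count V followed by C
  m <- 0L
  for (i in seq_along(runs)) {
    if (i > 1L && runs[i] && !runs[i - 1L]) m <- m + 1L
  }
  m
}

porter_contains_vowel <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(FALSE)
  any(!vapply(seq_len(n), function(i) porter_is_cons(chars, i), logical(1)))
}

porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  porter_is_cons(chars, n)
}

# *o: stem ends cvc where the final c is not w, x or y
porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  if (!porter_is_cons(chars, n) || porter_is_cons(chars, n - 1L) ||
      !porter_is_cons(chars, n - 2L)) {
    return(FALSE)
  }
  !(chars[n] %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  n <- nchar(word)
  k <- nchar(suffix)
  n > k && substr(word, n - k + 1L, n) == suffix
}

porter_chop <- function(word, suffix) {
  substr(word, 1L, nchar(word) - nchar(suffix))
}

# try rules (suffix -> replacement) requiring measure(stem) > min_m; returns
# the rewritten word, or NULL when no suffix matched
porter_rule <- function(word, rules, min_m) {
  for (r in rules) {
    if (porter_ends(word, r[[1]])) {
      stem <- porter_chop(word, r[[1]])
      if (porter_measure(stem) > min_m) {
        return(paste0(stem, r[[2]]))
      }
      return(word)
    }
  }
  NULL
}

#' Stem a word with the Porter algorithm
#'
#' Reduces an English word to its stem through the five suffix-stripping steps
#' of the Porter algorithm ("relational" -> "relat", "ponies" -> "poni").
#' Words of one or two characters are returned unchanged.
#'
#' @param word character vector of lowercase words.
#' @return character vector of stems, same length as `word`.
#' @export
#' @examples
#' porter_stem(c("traits", "placement", "divergent"))
porter_stem <- function(word) {
  vapply(word, porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # Step 1a
  if (porter_ends(word, "sses")) {
    word <- paste0(porter_chop(word, "sses"), "ss")
  } else if (porter_ends(word, "ies")) {
    word <- paste0(porter_chop(word, "ies"), "i")
  } else if (porter_ends(word, "ss")) {
    # unchanged
  } else if (porter_ends(word, "s")) {
    word <- porter_chop(word, "s")
  }

  # Step 1b
  step1b_cleanup <- FALSE
  if (porter_ends(word, "eed")) {
    stem <- porter_chop(word, "eed")
    if (porter_measure(stem) > 0L) word <- paste0(stem, "ee")
  } else if (porter_ends(word, "ed")) {
    stem <- porter_chop(word, "ed")
    if (porter_contains_vowel(stem)) {
      word <- stem
      step1b_cleanup <- TRUE
    }
  } else if (porter_ends(word, "ing")) {
    stem <- porter_chop(word, "ing")
    if (porter_contains_vowel(stem)) {
      word <- stem
      step1b_cleanup <- TRUE
    }
  }
  if (step1b_cleanup) {
    if (porter_ends(word, "at") || porter_ends(word, "bl") ||
        porter_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (porter_double_cons(word) &&
               !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z"))) {
      word <- substr(word, 1L, nchar(word) - 1L)
    } else if (porter_measure(word) == 1L && porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # Step 1c
  if (porter_ends(word, "y") && porter_contains_vowel(porter_chop(word, "y"))) {
    word <- paste0(porter_chop(word, "y"), "i")
  }

  # Step 2 (m > 0)
  rules2 <- list(
    list("ational", "ate"), list("tional", "tion"), list("enci", "ence"),
    list("anci", "ance"), list("izer", "ize"), list("abli", "able"),
    list("alli", "al"), list("entli", "ent"), list("eli", "e"),
    list("ousli", "ous"), list("ization", "ize"), list("ation", "ate"),
    list("ator", "ate"), list("alism", "al"), list("iveness", "ive"),
    list("fulness", "ful"), list("ousness", "ous"), list("aliti", "al"),
    list("iviti", "ive"), list("biliti", "ble")
  )
  res <- porter_rule(word, rules2, 0L)
  if (!is.null(res)) word <- res

  # Step 3 (m > 0)
  rules3 <- list(
    list("icate", "ic"), list("ative", ""), list("alize", "al"),
    list("iciti", "ic"), list("ical", "ic"), list("ful", ""), list("ness", "")
  )
  res <- porter_rule(word, rules3, 0L)
  if (!is.null(res)) word <- res

  # Step 4 (m > 1); "ion" additionally requires stem ending s or t
  rules4 <- c(
    "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
    "ment", "ent", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
  )
  matched4 <- FALSE
  if (porter_ends(word, "ion")) {
    stem <- porter_chop(word, "ion")
    last <- substr(stem, nchar(stem), nchar(stem))
    if (last %in% c("s", "t")) {
      matched4 <- TRUE
      if (porter_measure(stem) > 1L) word <- stem
    }
  }
  if (!matched4) {
    for (sfx in rules4) {
      if (porter_ends(word, sfx)) {
        stem <- porter_chop(word, sfx)
        if (porter_measure(stem) > 1L) word <- stem
        break
      }
    }
  }

  # Step 5a
  if (porter_ends(word, "e")) {
    stem <- porter_chop(word, "e")
    m <- porter_measure(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) word <- stem
  }
  # Step 5b
  if (porter_measure(word) > 1L && porter_double_cons(word) &&
      porter_ends(word, "l")) {
    word <- substr(word, 1L, nchar(word) - 1L)
  }

  word
}
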