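# Hybrid lexical similarity: thesaurus synonymy with a character n-gram
# fallback at the word level, aggregated over token sets by symmetric
# best-match averaging.

#' Character n-gram similarity between two words
#'
#' Dice coefficient over the multisets of character n-grams:
#' `2 * |common| / (|grams(w1)| + |grams(w2)|)`. A word shorter than `n`
#' contributes itself as a single gram, so very short words still compare
#' sensibly. Identical words always score 1.
#'
#' @param w1,w2 single words.
#' @param n gram length, an integer >= 1 (default 2, i.e. bigrams).
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' ngram_similarity("trait", "train") # 3 shared bigrams of 4 -> 0.75
ngram_similarity <- function(w1, w2, n = 2L) {
  if (!is_scalar_number(n) || n < 1) {
    stop("`n` must be an integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (identical(w1, w2)) return(1)
  g1 <- char_ngrams(w1, n)
  g2 <- char_ngrams(w2, n)
  if (!length(g1) || !length(g2)) return(0)
  2 * multiset_overlap(g1, g2) / (length(g1) + length(g2))
}

char_ngrams <- function(w, n) {
  len <- nchar(w)
  if (len == 0L) return(character(0))
  if (len < n) return(w)
  starts <- seq_len(len - n + 1L)
  substring(w, starts, starts + n - 1L)
}

multiset_overlap <- function(a, b) {
  ta <- table(a)
  tb <- table(b)
  shared <- intersect(names(ta), names(tb))
  if (!length(shared)) return(0L)
  sum(pmin(as.integer(ta[shared]), as.integer(tb[shared])))
}

#' Word-level similarity (thesaurus first, n-grams otherwise)
#'
#' Two words score 1 when they are literally equal or recorded as synonyms in
#' the thesaurus; otherwise the score is their [ngram_similarity()].
#'
#' @param w1,w2 normalized word tokens.
#' @param t a [thesaurus()].
#' @param n n-gram order passed to [ngram_similarity()].
#' @return similarity in `[0, 1]`.
#' @export
word_similarity <- function(w1, w2, t = thesaurus(), n = 2L) {
  if (are_synonyms(t, w1, w2)) return(1)
  ngram_similarity(w1, w2, n)
}

#' Symmetric best-match similarity of two token sets
#'
#' For token sets `W1` and `W2` the score is
#' `(sum_i max_j sim(w1i, w2j) + sum_j max_i sim(w1i, w2j)) / (|W1| + |W2|)`,
#' where `sim` is [word_similarity()]. Each word is credited with its best
#' counterpart on the other side, and the two directional sums are averaged by
#' total word count, which keeps the measure symmetric and in `[0, 1]`.
#'
#' Empty-set conventions: both sets empty scores 1 when the raw source labels
#' were equal and 0 otherwise; exactly one empty set scores 0.
#'
#' @param W1,W2 `token_set` objects from [preprocess_name()].
#' @param t a [thesaurus()].
#' @param n n-gram order.
#' @return similarity in `[0, 1]`.
#' @export
token_set_similarity <- function(W1, W2, t = thesaurus(), n = 2L) {
  stopifnot(inherits(W1, "token_set"), inherits(W2, "token_set"))
  a <- W1$words
  b <- W2$words
  if (!length(a) && !length(b)) {
    return(if (identical(W1$source, W2$source)) 1 else 0)
  }
  if (!length(a) || !length(b)) return(0)
  S <- word_sim_matrix(a, b, t, n)
  (sum(apply(S, 1L, max)) + sum(apply(S, 2L, max))) / (length(a) + length(b))
}

word_sim_matrix <- function(a, b, t, n) {
  S <- matrix(0, nrow = length(a), ncol = length(b))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      S[i, j] <- word_similarity(a[i], b[j], t, n)
    }
  }
  S
}

#' Hybrid entity similarity
#'
#' Confidence that two entities denote the same concept: both labels are
#' normalized with [preprocess_name()] and compared with
#' [token_set_similarity()]. The measure is symmetric, lies in `[0, 1]`, and
#' equals 1 for identical labels.
#'
#' @param e1,e2 entity labels (strings), or rows of an ontology's entity table.
#' @param t a [thesaurus()].
#' @param stop_words stop-word list for preprocessing.
#' @param n n-gram order.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' th <- fixture_thesaurus()
#' entity_similarity("Divergent tectonic movement", "Plate divergence", t = th)
entity_similarity <- function(e1, e2, t = thesaurus(),
                              stop_words = default_stopwords(), n = 2L) {
  name1 <- if (is.list(e1)) e1$name else e1
  name2 <- if (is.list(e2)) e2$name else e2
  token_set_similarity(
    preprocess_name(name1, stop_words, t),
    preprocess_name(name2, stop_words, t),
    t = t, n = n
  )
}

#' Entity similarity matrix between two ontologies
#'
#' Computes the full `|O1| x |O2|` confidence matrix used by the aligner.
#' Token sets are computed once per entity and word-level scores are cached
#' over the joint vocabulary, so the cost is one word-pair computation per
#' distinct stem pair.
#'
#' @param o1,o2 [ontology] objects (source in rows, target in columns).
#' @param t a [thesaurus()].
#' @param stop_words stop-word list.
#' @param n n-gram order.
#' @return numeric matrix with entity ids as dimnames.
#' @export
similarity_matrix <- function(o1, o2, t = thesaurus(),
                              stop_words = default_stopwords(), n = 2L) {
  stopifnot(inherits(o1, "ontology"), inherits(o2, "ontology"))
  ts1 <- lapply(o1$entities$name, preprocess_name, stop_words = stop_words,
                thesaurus = t)
  ts2 <- lapply(o2$entities$name, preprocess_name, stop_words = stop_words,
                thesaurus = t)
  vocab1 <- unique(unlist(lapply(ts1, `[[`, "words")))
  vocab2 <- unique(unlist(lapply(ts2, `[[`, "words")))
  W <- matrix(0, length(vocab1), length(vocab2),
              dimnames = list(vocab1, vocab2))
  for (i in seq_along(vocab1)) {
    for (j in seq_along(vocab2)) {
      W[i, j] <- word_similarity(vocab1[i], vocab2[j], t, n)
    }
  }
  M <- matrix(0, ontology_size(o1), ontology_size(o2),
              dimnames = list(o1$entities$id, o2$entities$id))
  for (i in seq_len(nrow(M))) {
    a <- ts1[[i]]$words
    for (j in seq_len(ncol(M))) {
      b <- ts2[[j]]$words
      if (!length(a) && !length(b)) {
        M[i, j] <- if (identical(ts1[[i]]$source, ts2[[j]]$source)) 1 else 0
      } else if (!length(a) || !length(b)) {
        M[i, j] <- 0
      } else {
        S <- W[a, b, drop = FALSE]
        M[i, j] <- (sum(apply(S, 1L, max)) + sum(apply(S, 2L, max))) /
          (length(a) + length(b))
      }
    }
  }
  M
}
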