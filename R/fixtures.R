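# Synthetic benchmark generator: pairs of overlapping concept hierarchies
# whose matched labels differ by synonym substitution, token reordering,
# affix noise and stop-word insertion -- the heterogeneity patterns seen
# between real ecology/biodiversity ontologies (ENVO vs SWEET, FLOPO vs PTO)
# -- together with the known reference alignment.

#' Specification of a synthetic ontology pair
#'
#' The defaults describe the standard benchmark condition used throughout the
#' package: 40 source concepts in a branching-3 tree, moderate lexical
#' perturbation (30% synonym swaps, 30% token shuffles, 20% affix noise, 30%
#' stop-word insertion) and 10% concept deletion on the target side.
#'
#' @param n_concepts number of source concepts (>= 1).
#' @param branching maximum children per concept in the generated tree.
#' @param synonym_rate probability that one label word is replaced by a
#'   synonym from the bundled fixture thesaurus.
#' @param shuffle_rate probability that the label's words are reordered.
#' @param affix_rate probability that one word receives a spurious affix.
#' @param stopword_rate probability that a stop-word is inserted.
#' @param deletion_rate probability that a (non-root) concept is missing from
#'   the target ontology.
#' @param words_per_label candidate label lengths in words.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_concepts = 40L, branching = 3L,
                         synonym_rate = 0.3, shuffle_rate = 0.3,
                         affix_rate = 0.2, stopword_rate = 0.3,
                         deletion_rate = 0.1, words_per_label = 2:3,
                         seed = 1L) {
  rates <- c(synonym_rate = synonym_rate, shuffle_rate = shuffle_rate,
             affix_rate = affix_rate, stopword_rate = stopword_rate,
             deletion_rate = deletion_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("perturbation rates must lie in [0, 1]", call. = FALSE)
  }
  if (!is_scalar_number(n_concepts) || n_concepts < 1) {
    stop("`n_concepts` must be >= 1", call. = FALSE)
  }
  structure(
    list(n_concepts = as.integer(n_concepts), branching = as.integer(branching),
         synonym_rate = synonym_rate, shuffle_rate = shuffle_rate,
         affix_rate = affix_rate, stopword_rate = stopword_rate,
         deletion_rate = deletion_rate, words_per_label = words_per_label,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

fixture_vocabulary <- function() {
  readLines(system.file("extdata", "vocabulary.txt", package = "acealign"),
            warn = FALSE)
}

# raw (unstemmed) synonym partner map used by the synonym-swap operator
fixture_synonym_map <- function() {
  path <- system.file("extdata", "fixture_thesaurus.csv", package = "acealign")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df$word2, df$word1)
}

#' Generate a synthetic ontology pair with a known reference alignment
#'
#' Builds a random tree-shaped source ontology with multi-word labels drawn
#' from the bundled vocabulary, then derives the target ontology as a copy
#' whose labels are perturbed per the spec (synonym substitution via the
#' bundled fixture thesaurus, token reordering, affix noise, stop-word
#' insertion) and from which a fraction of concepts is deleted (children are
#' re-attached to their nearest surviving ancestor). The target entity order
#' is permuted. The reference alignment consists of the surviving identity
#' pairs at confidence 1.
#'
#' @param spec a [fixture_spec()].
#' @return list with `o1`, `o2` ([ontology][new_ontology] objects) and
#'   `reference` (an [alignment][new_alignment]).
#' @export
#' @examples
#' fx <- generate_fixture_pair(fixture_spec(n_concepts = 8, seed = 3))
#' fx$reference
generate_fixture_pair <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, generate_fixture_pair_impl(spec))
}

generate_fixture_pair_impl <- function(spec) {
  vocab <- fixture_vocabulary()
  syn <- fixture_synonym_map()
  n <- spec$n_concepts

  # unique multi-word labels
  labels <- list()
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      k <- if (length(spec$words_per_label) == 1L) spec$words_per_label else
        sample(spec$words_per_label, 1L)
      ws <- sample(vocab, k)
      key <- paste(sort(ws), collapse = " ")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        labels[[i]] <- ws
        break
      }
    }
  }

  # random tree with bounded branching; node 1 is the root
  parent <- integer(n)
  child_count <- integer(n)
  for (i in seq_len(n)[-1]) {
    open <- which(child_count[seq_len(i - 1L)] < spec$branching)
    p <- if (length(open)) open[sample.int(length(open), 1L)] else
      sample.int(i - 1L, 1L)
    parent[i] <- p
    child_count[p] <- child_count[p] + 1L
  }

  src_ids <- sprintf("s%03d", seq_len(n))
  o1 <- new_ontology(
    data.frame(id = src_ids,
               name = vapply(labels, compose_label, character(1)),
               stringsAsFactors = FALSE),
    data.frame(child = src_ids[seq_len(n)[-1]],
               parent = src_ids[parent[seq_len(n)[-1]]]),
    name = "synthetic-source"
  )

  # target-side label perturbation
  stop_pool <- c("of", "the", "in", "with", "a")
  affixes <- c("al", "ic", "ous", "ness", "oid")
  t_labels <- lapply(labels, function(ws) {
    if (stats::runif(1) < spec$synonym_rate) {
      cand <- which(ws %in% names(syn))
      if (length(cand)) {
        k <- cand[sample.int(length(cand), 1L)]
        partners <- syn[[ws[k]]]
        ws[k] <- partners[sample.int(length(partners), 1L)]
      }
    }
    if (length(ws) > 1L && stats::runif(1) < spec$shuffle_rate) {
      ws <- ws[sample.int(length(ws))]
    }
    if (stats::runif(1) < spec$affix_rate) {
      k <- sample.int(length(ws), 1L)
      ws[k] <- paste0(ws[k], affixes[sample.int(length(affixes), 1L)])
    }
    if (stats::runif(1) < spec$stopword_rate) {
      pos <- sample.int(length(ws) + 1L, 1L) - 1L
      ws <- append(ws, stop_pool[sample.int(length(stop_pool), 1L)], after = pos)
    }
    ws
  })

  # concept deletion (root survives) and re-attachment
  deleted <- stats::runif(n) < spec$deletion_rate
  deleted[1L] <- FALSE
  survivors <- which(!deleted)
  surviving_ancestor <- function(i) {
    p <- parent[i]
    while (p != 0L && deleted[p]) p <- parent[p]
    p
  }

  perm <- survivors[sample.int(length(survivors))]
  tgt_ids <- setNames(sprintf("t%03d", seq_along(perm)), perm)
  t_edges <- do.call(rbind, lapply(perm, function(i) {
    p <- surviving_ancestor(i)
    if (p == 0L) return(NULL)
    data.frame(child = tgt_ids[[as.character(i)]],
               parent = tgt_ids[[as.character(p)]],
               stringsAsFactors = FALSE)
  }))
  o2 <- new_ontology(
    data.frame(id = unname(tgt_ids),
               name = vapply(t_labels[perm], compose_label, character(1)),
               stringsAsFactors = FALSE),
    t_edges,
    name = "synthetic-target"
  )

  reference <- new_alignment(
    data.frame(e1 = src_ids[perm], e2 = unname(tgt_ids), conf = 1,
               stringsAsFactors = FALSE),
    source = o1$name, target = o2$name
  )
  list(o1 = o1, o2 = o2, reference = reference)
}

compose_label <- function(ws) {
  lab <- paste(ws, collapse = " ")
  paste0(toupper(substr(lab, 1L, 1L)), substr(lab, 2L, nchar(lab)))
}

#' The six-entity crisscross fixture
#'
#' Two three-concept chain hierarchies (`a3` subsumed by `a1` subsumed by
#' `a2`; likewise `b3`/`b1`/`b2`) with the positive anchor `(a1, b1)`. On
#' this configuration the candidates `(a2, b3)` and `(a3, b2)` each invert a
#' subsumption relation across the pair and are exactly the correspondences
#' that contradict the anchor; all reasoning tests are anchored on it.
#'
#' @return list with `o1`, `o2` and `anchor` (a one-row
#'   [alignment][new_alignment] at confidence 1).
#' @export
fig2_fixture <- function() {
  o1 <- new_ontology(
    data.frame(id = c("a1", "a2", "a3"), name = c("a1", "a2", "a3"),
               stringsAsFactors = FALSE),
    data.frame(child = c("a3", "a1"), parent = c("a1", "a2")),
    name = "crisscross-source"
  )
  o2 <- new_ontology(
    data.frame(id = c("b1", "b2", "b3"), name = c("b1", "b2", "b3"),
               stringsAsFactors = FALSE),
    data.frame(child = c("b3", "b1"), parent = c("b1", "b2")),
    name = "crisscross-target"
  )
  anchor <- new_alignment(
    data.frame(e1 = "a1", e2 = "b1", conf = 1, stringsAsFactors = FALSE),
    source = o1$name, target = o2$name
  )
  list(o1 = o1, o2 = o2, anchor = anchor)
}

#' Write a fixture pair to disk
#'
#' Emits the two ontologies in the tabular dialect (`source.csv`,
#' `target.csv`) and the reference alignment in the OAEI Alignment RDF format
#' with its CSV sidecar (`reference.rdf`, `reference.csv`).
#'
#' @param fx result of [generate_fixture_pair()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_pair <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    source = file.path(dir, "source.csv"),
    target = file.path(dir, "target.csv"),
    reference = file.path(dir, "reference.rdf")
  )
  write_toy_table(fx$o1, paths[["source"]])
  write_toy_table(fx$o2, paths[["target"]])
  write_alignment(fx$reference, paths[["reference"]])
  invisible(paths)
}
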