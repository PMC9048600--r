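# Anchor-based semantic reasoning: positive anchors (very confident
# correspondences) forbid "crisscross" candidates that invert a subsumption
# relation across the pair of hierarchies; negative anchors (very unlikely
# correspondences found in an elite individual) trigger probability decay in
# their hierarchical neighborhood.

#' Detect positive and negative anchor correspondences
#'
#' Positive anchors (PAs) are entity pairs whose similarity reaches
#' `pa_threshold`, filtered to a 1:1 set greedily by descending confidence;
#' they are treated as near-certain and used to prune contradicting
#' candidates. Negative anchors (NAs) are pairs below `na_threshold`; during
#' evolution they are only meaningful among the correspondences of the
#' current elite individual, so when `elite` is supplied the negatives are
#' restricted to its 1-cells.
#'
#' @param sims numeric similarity matrix (entity ids as dimnames).
#' @param pa_threshold confidence at and above which a pair is a positive
#'   anchor (default 0.95).
#' @param na_threshold confidence below which a pair is a negative anchor
#'   (default 0.2); must be strictly less than `pa_threshold`.
#' @param elite optional 0-1 matrix restricting negative anchors to its
#'   1-cells.
#' @return object of class `anchor_set`: list with `positive` and `negative`
#'   (each an [alignment][new_alignment]) and the thresholds used.
#' @export
detect_anchors <- function(sims, pa_threshold = 0.95, na_threshold = 0.2,
                           elite = NULL) {
  stop_if_not_scalar_prob(pa_threshold, "pa_threshold")
  stop_if_not_scalar_prob(na_threshold, "na_threshold")
  if (na_threshold >= pa_threshold) {
    stop("`na_threshold` must be strictly below `pa_threshold`",
         call. = FALSE)
  }
  pos_mask <- (sims >= pa_threshold) * 1
  pos_mask <- enforce_single_cardinality(pos_mask, sims)
  positive <- matrix_to_alignment(pos_mask, sims)

  neg_cells <- sims < na_threshold
  if (!is.null(elite)) {
    stopifnot(identical(dim(elite), dim(sims)))
    neg_cells <- neg_cells & (elite == 1)
  }
  negative <- matrix_to_alignment(neg_cells * 1, sims)
  structure(
    list(positive = positive, negative = negative,
         pa_threshold = pa_threshold, na_threshold = na_threshold),
    class = "anchor_set"
  )
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf(
    "<anchor_set: %d positive (conf >= %.2f), %d negative (conf < %.2f)>\n",
    nrow(x$positive), x$pa_threshold, nrow(x$negative), x$na_threshold))
  invisible(x)
}

#' Does a correspondence logically contradict an anchor?
#'
#' A candidate `(m, n)` contradicts an anchor `(i, j)` when it crosses the
#' subsumption hierarchies: `m` is a strict ancestor of `i` while `n` is a
#' strict descendant of `j`, or vice versa. Mapping an ancestor on one side to
#' a descendant on the other is inconsistent with the anchor under
#' subsumption. The relation is symmetric in its two arguments and a
#' correspondence never contradicts itself.
#'
#' @param c,anchor correspondences: lists/rows with elements `e1`, `e2`
#'   (entity ids), or length-2 character vectors `(e1, e2)`.
#' @param o1,o2 source/target [ontology][new_ontology] objects.
#' @return logical scalar.
#' @export
#' @examples
#' fx <- fig2_fixture()
#' contradicts(c("a2", "b3"), fx$anchor, fx$o1, fx$o2) # TRUE
contradicts <- function(c, anchor, o1, o2) {
  ce <- corr_pair(c)
  ae <- corr_pair(anchor)
  check_entity(o1, ce[1]); check_entity(o2, ce[2])
  check_entity(o1, ae[1]); check_entity(o2, ae[2])
  (ce[1] %in% ancestors(o1, ae[1]) && ce[2] %in% descendants(o2, ae[2])) ||
    (ce[1] %in% descendants(o1, ae[1]) && ce[2] %in% ancestors(o2, ae[2]))
}

corr_pair <- function(x) {
  if (is.character(x) && length(x) == 2L) return(x)
  c(as.character(x$e1), as.character(x$e2))
}

#' Contradiction pruning mask
#'
#' Builds a 0-1 mask of shape `|O1| x |O2|` whose cell is 0 exactly when the
#' corresponding candidate pair contradicts at least one positive anchor
#' ([contradicts()]). Multiplying a probability or aligning matrix by the mask
#' removes the forbidden region from the search space. An anchor's own cell is
#' never masked.
#'
#' @param o1,o2 source/target [ontology][new_ontology] objects.
#' @param pas positive anchors: an [alignment][new_alignment] (e.g.
#'   `detect_anchors(...)$positive`) or a data frame with `e1`, `e2`.
#' @return 0-1 matrix with entity ids as dimnames.
#' @export
prune_mask <- function(o1, o2, pas) {
  mask <- matrix(1, ontology_size(o1), ontology_size(o2),
                 dimnames = list(o1$entities$id, o2$entities$id))
  if (is.null(pas) || nrow(pas) == 0L) return(mask)
  anc1 <- ancestor_matrix(o1)
  anc2 <- ancestor_matrix(o2)
  for (k in seq_len(nrow(pas))) {
    p <- as.character(pas$e1[k])
    q <- as.character(pas$e2[k])
    # rows that are ancestors (resp. descendants) of the anchor's source side
    anc_p <- anc1[p, ]          # m is ancestor of p
    desc_p <- anc1[, p]         # m is descendant of p
    anc_q <- anc2[q, ]
    desc_q <- anc2[, q]
    mask[outer(anc_p, desc_q, "&") | outer(desc_p, anc_q, "&")] <- 0
  }
  mask
}

#' Neighbor correspondences within a hierarchy radius
#'
#' All pairs `(em, en)` whose two entities lie within undirected shortest-path
#' distance `radius` of the entities of `c` in their respective hierarchy
#' graphs, excluding `c` itself. With the default radius 1 this is the
#' "shortest path less than 2" neighborhood used for negative-anchor decay.
#'
#' @param c a correspondence (see [contradicts()]).
#' @param o1,o2 source/target ontologies.
#' @param radius non-negative integer (default 1).
#' @return data frame with columns `e1`, `e2`, one row per neighbor pair.
#' @export
neighbor_correspondences <- function(c, o1, o2, radius = 1L) {
  if (!is_scalar_number(radius) || radius < 0) {
    stop("`radius` must be a non-negative integer", call. = FALSE)
  }
  ce <- corr_pair(c)
  check_entity(o1, ce[1])
  check_entity(o2, ce[2])
  n1 <- entities_within(o1, ce[1], radius)
  n2 <- entities_within(o2, ce[2], radius)
  out <- expand.grid(e1 = n1, e2 = n2, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out[!(out$e1 == ce[1] & out$e2 == ce[2]), , drop = FALSE]
}

entities_within <- function(o, e, radius) {
  if (radius == 0L) return(e)
  vs <- igraph::V(o$graph)$name
  if (!(e %in% vs)) return(e)
  igraph::ego(o$graph, order = radius, nodes = e, mode = "all")[[1]]$name
}
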