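# Independent brute-force oracles and small builders shared across tests.
# These deliberately avoid the package's own code paths (and igraph) so that
# agreement is meaningful.

# random DAG as an edge list child -> parent over ids v1..vn; edges only go
# from higher to lower index, which guarantees acyclicity
random_dag <- function(n, p_edge = 0.15) {
  edges <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (runif(1) < p_edge) {
        edges <- rbind(edges, data.frame(child = paste0("v", i),
                                         parent = paste0("v", j)))
      }
    }
  }
  list(
    entities = data.frame(id = paste0("v", seq_len(n)),
                          name = paste0("node ", seq_len(n))),
    edges = if (is.null(edges)) {
      data.frame(child = character(0), parent = character(0))
    } else {
      edges
    }
  )
}

ontology_from_dag <- function(dag, name = "dag") {
  new_ontology(dag$entities, dag$edges, name = name)
}

# plain recursive DFS reachability over the child -> parent edge list
dfs_reachable <- function(edges, from) {
  seen <- character(0)
  stack <- from
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    nxt <- setdiff(edges$parent[edges$child == v], seen)
    seen <- union(seen, nxt)
    stack <- c(stack, nxt)
  }
  setdiff(seen, from)
}

# breadth-first shortest path length on the undirected edge view
bfs_distance <- function(edges, ids, a, b) {
  if (a == b) return(0)
  adj <- lapply(setNames(ids, ids), function(v) {
    unique(c(edges$parent[edges$child == v], edges$child[edges$parent == v]))
  })
  dist <- setNames(rep(Inf, length(ids)), ids)
  dist[a] <- 0
  queue <- a
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        if (w == b) return(unname(dist[w]))
        queue <- c(queue, w)
      }
    }
  }
  unname(dist[b])
}

# literal double-loop evaluation of the symmetric best-match set similarity
eq2_oracle <- function(a, b, wordsim) {
  if (!length(a) && !length(b)) return(NA_real_) # caller decides empty case
  if (!length(a) || !length(b)) return(0)
  s1 <- 0
  for (w1 in a) {
    best <- 0
    for (w2 in b) best <- max(best, wordsim(w1, w2))
    s1 <- s1 + best
  }
  s2 <- 0
  for (w2 in b) {
    best <- 0
    for (w1 in a) best <- max(best, wordsim(w1, w2))
    s2 <- s2 + best
  }
  (s1 + s2) / (length(a) + length(b))
}

# brute-force character bigram Dice
bigram_dice_oracle <- function(w1, w2) {
  if (identical(w1, w2)) return(1)
  grams <- function(w) {
    if (nchar(w) == 0L) return(character(0))
    if (nchar(w) < 2L) return(w)
    out <- character(0)
    for (i in seq_len(nchar(w) - 1L)) out <- c(out, substr(w, i, i + 1L))
    out
  }
  g1 <- grams(w1)
  g2 <- grams(w2)
  if (!length(g1) || !length(g2)) return(0)
  common <- 0L
  pool <- g2
  for (g in g1) {
    hit <- match(g, pool)
    if (!is.na(hit)) {
      common <- common + 1L
      pool <- pool[-hit]
    }
  }
  2 * common / (length(g1) + length(g2))
}

make_token_set <- function(words, source = paste(words, collapse = " ")) {
  structure(list(words = words, source = source), class = "token_set")
}

# tiny identical ontology pair whose optimum is the identity alignment
identical_toy_pair <- function(n = 6L) {
  labels <- paste("concept", letters[seq_len(n)])
  ids1 <- paste0("x", seq_len(n))
  ids2 <- paste0("y", seq_len(n))
  edges <- function(ids) {
    # binary-heap shaped tree: parent of node k is node floor(k / 2)
    data.frame(child = ids[2:n], parent = ids[(2:n) %/% 2L])
  }
  o1 <- new_ontology(data.frame(id = ids1, name = labels), edges(ids1), name = "toyA")
  o2 <- new_ontology(data.frame(id = ids2, name = labels), edges(ids2), name = "toyB")
  ref <- new_alignment(data.frame(e1 = ids1, e2 = ids2, conf = 1))
  list(o1 = o1, o2 = o2, reference = ref)
}
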