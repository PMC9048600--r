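#' Ontology objects
#'
#' An `ontology` holds an ordered entity table and the subsumption hierarchy
#' over its concepts. Entities are concepts (classes) and, optionally,
#' datatype/object properties; only concepts take part in the hierarchy and in
#' contradiction reasoning. The entity order is stable and defines the
#' row/column index of every matrix built over the ontology.
#'
#' @param entities data frame with columns `id` (unique identifier), `name`
#'   (label; empty labels fall back to the id's local fragment) and optionally
#'   `kind` (one of `"concept"`, `"datatype-property"`, `"object-property"`;
#'   default `"concept"`).
#' @param edges data frame with columns `child`, `parent`: each row is one
#'   subsumption axiom "child is subsumed by parent". May have zero rows.
#' @param annotations optional list (parallel to `entities`) of character
#'   vectors of annotation text (definitions, alternate labels).
#' @param name optional display name of the ontology.
#' @return object of class `ontology`: list with `entities`, `annotations`,
#'   `graph` (directed [igraph][igraph::graph_from_data_frame] graph, edges
#'   pointing from child to parent) and `name`.
#' @export
#' @examples
#' o <- new_ontology(
#'   data.frame(id = c("a2", "a1", "a3"), name = c("root", "mid", "leaf")),
#'   data.frame(child = c("a1", "a3"), parent = c("a2", "a1"))
#' )
#' ancestors(o, "a3")
new_ontology <- function(entities, edges = NULL, annotations = NULL,
                         name = "ontology") {
  if (is.null(entities) || nrow(entities) == 0L) {
    entities <- data.frame(id = character(0), name = character(0),
                           kind = character(0), stringsAsFactors = FALSE)
  }
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(entities))) {
    stop("`entities` needs columns `id` and `name`", call. = FALSE)
  }
  entities$id <- as.character(entities$id)
  entities$name <- as.character(entities$name)
  if (is.null(entities$kind)) entities$kind <- rep("concept", nrow(entities))
  if (anyDuplicated(entities$id)) {
    dup <- entities$id[duplicated(entities$id)][1]
    stop("duplicate entity id: ", dup, call. = FALSE)
  }
  # empty labels fall back to the local fragment of the id
  blank <- !nzchar(trimws(entities$name))
  if (any(blank)) entities$name[blank] <- local_fragment(entities$id[blank])

  if (is.null(annotations)) annotations <- vector("list", nrow(entities))
  stopifnot(length(annotations) == nrow(entities))

  concepts <- entities$id[entities$kind == "concept"]
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(child = character(0), parent = character(0),
                        stringsAsFactors = FALSE)
  }
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(edges$child, edges$parent)), concepts)
  if (length(unknown)) {
    stop("hierarchy edge endpoint is not a known concept: ", unknown[1],
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = concepts, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    cyc <- find_cycle_edge(g)
    stop(sprintf("cyclic subsumption: edge %s -> %s lies on a cycle",
                 cyc[1], cyc[2]), call. = FALSE)
  }
  structure(
    list(entities = entities, annotations = annotations, graph = g,
         name = name),
    class = "ontology"
  )
}

local_fragment <- function(id) {
  sub(".*[#/]", "", id)
}

# return c(child, parent) for one edge lying on a directed cycle
find_cycle_edge <- function(g) {
  el <- igraph::as_edgelist(g)
  for (k in seq_len(nrow(el))) {
    # edge u->v is on a cycle iff v reaches u
    reach <- igraph::subcomponent(g, el[k, 2], mode = "out")$name
    if (el[k, 1] %in% reach) return(el[k, ])
  }
  el[1, ]
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology '%s': %d entities, %d subsumption edge(s)>\n",
              x$name, nrow(x$entities), igraph::ecount(x$graph)))
  invisible(x)
}

#' Number of alignable entities
#' @param o an [ontology][new_ontology].
#' @return integer count.
#' @export
ontology_size <- function(o) {
  stopifnot(inherits(o, "ontology"))
  nrow(o$entities)
}

check_entity <- function(o, e) {
  e <- as.character(e)
  if (!(e %in% o$entities$id)) {
    stop("unknown entity: ", e, call. = FALSE)
  }
  e
}

#' Transitive ancestors of a concept
#'
#' All concepts that (transitively) subsume `e`, excluding `e` itself.
#'
#' @param o an [ontology][new_ontology].
#' @param e entity id.
#' @return character vector of entity ids.
#' @export
ancestors <- function(o, e) {
  e <- check_entity(o, e)
  if (!(e %in% igraph::V(o$graph)$name)) return(character(0))
  setdiff(igraph::subcomponent(o$graph, e, mode = "out")$name, e)
}

#' Transitive descendants of a concept
#'
#' All concepts (transitively) subsumed by `e`, excluding `e` itself.
#'
#' @inheritParams ancestors
#' @return character vector of entity ids.
#' @export
descendants <- function(o, e) {
  e <- check_entity(o, e)
  if (!(e %in% igraph::V(o$graph)$name)) return(character(0))
  setdiff(igraph::subcomponent(o$graph, e, mode = "in")$name, e)
}

#' Shortest-path distance in the hierarchy graph
#'
#' Length of the shortest path between two concepts in the undirected view of
#' the subsumption graph; 0 iff the entities are equal, `Inf` when
#' disconnected.
#'
#' @inheritParams ancestors
#' @param a,b entity ids.
#' @return non-negative number, possibly `Inf`.
#' @export
graph_distance <- function(o, a, b) {
  a <- check_entity(o, a)
  b <- check_entity(o, b)
  if (identical(a, b)) return(0)
  vs <- igraph::V(o$graph)$name
  if (!(a %in% vs) || !(b %in% vs)) return(Inf)
  as.numeric(igraph::distances(o$graph, v = a, to = b, mode = "all"))
}

# Logical n x n matrix A with A[x, y] TRUE iff y is a (strict, transitive)
# ancestor of x. Rows/columns follow entity order; non-concept entities have
# all-FALSE rows and columns.
ancestor_matrix <- function(o) {
  ids <- o$entities$id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  vs <- igraph::V(o$graph)$name
  if (length(vs)) {
    D <- igraph::distances(o$graph, v = vs, to = vs, mode = "out")
    reach <- is.finite(D)
    diag(reach) <- FALSE
    A[vs, vs] <- reach
  }
  A
}

# List (per entity, in order) of entity ids within undirected hierarchy
# distance <= radius, including the entity itself.
neighborhood_list <- function(o, radius = 1L) {
  ids <- o$entities$id
  out <- as.list(ids)
  names(out) <- ids
  vs <- igraph::V(o$graph)$name
  if (length(vs) && radius > 0L) {
    nb <- igraph::ego(o$graph, order = radius, nodes = vs, mode = "all")
    for (k in seq_along(vs)) out[[vs[k]]] <- nb[[k]]$name
  }
  out
}

#' Load an ontology from a file
#'
#' Two dialects are supported: OWL serialized as RDF/XML (named classes with
#' `rdfs:label` and `rdfs:subClassOf` axioms), and a minimal tabular dialect
#' for fixtures — a UTF-8 CSV with header `id,label,parent` and one concept per
#' row (empty `parent` marks a root). With `dialect = "auto"` the format is
#' inferred from the file extension (`.owl`, `.rdf`, `.xml` vs anything else).
#'
#' Entity order is the document order of the file, so reloading the same file
#' always yields the same matrix indexing.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"owl-rdf"` or `"toy-table"`.
#' @param include_properties also load datatype/object properties as alignable
#'   entities (OWL dialect only). Properties never enter the hierarchy graph.
#' @return an [ontology][new_ontology].
#' @export
load_ontology <- function(path, dialect = c("auto", "owl-rdf", "toy-table"),
                          include_properties = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read ontology file: ", path, call. = FALSE)
  if (dialect == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    dialect <- if (ext %in% c("owl", "rdf", "xml")) "owl-rdf" else "toy-table"
  }
  switch(dialect,
    "toy-table" = read_toy_table(path),
    "owl-rdf" = read_owl_rdfxml(path, include_properties = include_properties)
  )
}

read_toy_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("id", "label", "parent") %in% names(df))) {
    stop("toy-table file needs header `id,label,parent`: ", path,
         call. = FALSE)
  }
  entities <- data.frame(id = df$id, name = df$label,
                         kind = rep("concept", nrow(df)),
                         stringsAsFactors = FALSE)
  has_parent <- nzchar(trimws(df$parent))
  edges <- data.frame(child = df$id[has_parent],
                      parent = trimws(df$parent[has_parent]),
                      stringsAsFactors = FALSE)
  new_ontology(entities, edges,
               name = tools::file_path_sans_ext(basename(path)))
}

#' Write an ontology in the tabular dialect
#'
#' Emits the `id,label,parent` CSV read back by [load_ontology()]. A concept
#' with several parents is written once per parent edge on the first line and
#' additional parents are dropped with a warning (the tabular dialect is
#' tree-shaped); fixture ontologies are trees, so this does not arise for
#' generated data.
#'
#' @param o an [ontology][new_ontology].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_toy_table <- function(o, path) {
  stopifnot(inherits(o, "ontology"))
  el <- igraph::as_edgelist(o$graph)
  parent <- setNames(rep("", nrow(o$entities)), o$entities$id)
  if (nrow(el)) {
    dup <- duplicated(el[, 1])
    if (any(dup)) {
      warning("multi-parent concept(s) written with first parent only")
    }
    first <- el[!dup, , drop = FALSE]
    parent[first[, 1]] <- first[, 2]
  }
  df <- data.frame(id = o$entities$id, label = o$entities$name,
                   parent = unname(parent[o$entities$id]),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_owl_rdfxml <- function(path, include_properties = FALSE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse RDF/XML: ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl = "http://www.w3.org/2002/07/owl#"
  )
  grab <- function(xpath) xml2::xml_find_all(doc, xpath, ns)

  classes <- grab("//owl:Class[@rdf:about]")
  ids <- xml2::xml_attr(classes, "about")
  labels <- vapply(classes, function(node) {
    lab <- xml2::xml_find_first(node, "./rdfs:label", ns)
    if (inherits(lab, "xml_missing")) "" else xml2::xml_text(lab)
  }, character(1))
  annots <- lapply(classes, function(node) {
    cm <- xml2::xml_find_all(node, "./rdfs:comment", ns)
    if (length(cm)) xml2::xml_text(cm) else character(0)
  })

  # document order with duplicate declarations merged (first wins)
  keep <- !duplicated(ids)
  ids <- ids[keep]
  labels <- labels[keep]
  annots <- annots[keep]
  classes <- classes[keep]

  edges <- do.call(rbind, lapply(seq_along(classes), function(k) {
    sup <- xml2::xml_find_all(classes[[k]], "./rdfs:subClassOf[@rdf:resource]",
                              ns)
    if (!length(sup)) return(NULL)
    data.frame(child = ids[k], parent = xml2::xml_attr(sup, "resource"),
               stringsAsFactors = FALSE)
  }))
  entities <- data.frame(id = ids, name = labels, kind = "concept",
                         stringsAsFactors = FALSE)

  if (include_properties) {
    for (spec in list(c("owl:DatatypeProperty", "datatype-property"),
                      c("owl:ObjectProperty", "object-property"))) {
      nodes <- grab(sprintf("//%s[@rdf:about]", spec[1]))
      if (length(nodes)) {
        pid <- xml2::xml_attr(nodes, "about")
        plab <- vapply(nodes, function(node) {
          lab <- xml2::xml_find_first(node, "./rdfs:label", ns)
          if (inherits(lab, "xml_missing")) "" else xml2::xml_text(lab)
        }, character(1))
        keep <- !(pid %in% entities$id) & !duplicated(pid)
        entities <- rbind(entities,
                          data.frame(id = pid[keep], name = plab[keep],
                                     kind = spec[2], stringsAsFactors = FALSE))
        annots <- c(annots, vector("list", sum(keep)))
      }
    }
  }
  if (!is.null(edges)) {
    # drop subclass axioms pointing at undeclared (e.g. imported) classes
    edges <- edges[edges$parent %in% entities$id, , drop = FALSE]
  }
  new_ontology(entities, edges, annotations = annots,
               name = tools::file_path_sans_ext(basename(path)))
}
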