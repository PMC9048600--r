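#' Alignments and correspondences
#'
#' An alignment is a set of correspondences `(e1, e2, rel, conf)` between a
#' source and a target ontology; the relation is fixed to equivalence and
#' `conf` in `[0, 1]` is the confidence (typically the entity similarity).
#'
#' @param correspondences data frame with columns `e1`, `e2` (entity ids) and
#'   `conf` (confidence in `[0, 1]`); zero rows for the empty alignment.
#' @param source,target names of the source/target ontologies (informational).
#' @return object of class `alignment`: the correspondence data frame with a
#'   `rel` column fixed to `"="` and attributes `source`/`target`.
#' @export
new_alignment <- function(correspondences = NULL, source = "O1",
                          target = "O2") {
  if (is.null(correspondences) || nrow(correspondences) == 0L) {
    correspondences <- data.frame(e1 = character(0), e2 = character(0),
                                  conf = numeric(0), stringsAsFactors = FALSE)
  }
  df <- data.frame(e1 = as.character(correspondences$e1),
                   e2 = as.character(correspondences$e2),
                   rel = rep("=", nrow(correspondences)),
                   conf = as.numeric(correspondences$conf),
                   stringsAsFactors = FALSE)
  if (nrow(df) && (anyNA(df$conf) || any(df$conf < 0) || any(df$conf > 1))) {
    stop("correspondence confidences must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(paste(df$e1, df$e2, sep = "\r"))) {
    stop("duplicate correspondence (e1, e2) pair", call. = FALSE)
  }
  structure(df, class = c("alignment", "data.frame"),
            source = source, target = target)
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment %s -> %s: %d correspondence(s)>\n",
              attr(x, "source"), attr(x, "target"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Alignment size
#' @param A an [alignment][new_alignment].
#' @return number of correspondences.
#' @export
alignment_size <- function(A) nrow(A)

#' Decode a 0-1 aligning matrix into an alignment
#'
#' Every 1-cell of `M` becomes one correspondence whose confidence is the
#' matching cell of `sims`; this inverts the matrix encoding of an alignment
#' (source entities in rows, target entities in columns).
#'
#' @param M 0-1 matrix with entity ids as dimnames.
#' @param sims numeric similarity matrix of the same shape (confidence
#'   lookup); must be defined (non-`NA`) at every 1-cell.
#' @param source,target ontology names recorded on the result.
#' @return an [alignment][new_alignment].
#' @export
matrix_to_alignment <- function(M, sims, source = "O1", target = "O2") {
  stopifnot(is.matrix(M))
  if (!identical(dim(M), dim(sims))) {
    stop("`M` and `sims` must have the same shape", call. = FALSE)
  }
  ones <- which(M == 1, arr.ind = TRUE)
  if (nrow(ones) && anyNA(sims[ones])) {
    stop("similarity undefined for a selected cell", call. = FALSE)
  }
  new_alignment(
    data.frame(e1 = rownames(M)[ones[, 1]],
               e2 = colnames(M)[ones[, 2]],
               conf = sims[ones],
               stringsAsFactors = FALSE),
    source = source, target = target
  )
}

#' Encode an alignment as a 0-1 aligning matrix
#'
#' @param A an [alignment][new_alignment].
#' @param o1,o2 source and target [ontology][new_ontology] objects; their
#'   entity order defines rows and columns.
#' @return 0-1 matrix of shape `|O1| x |O2|` with id dimnames.
#' @export
alignment_to_matrix <- function(A, o1, o2) {
  M <- matrix(0, ontology_size(o1), ontology_size(o2),
              dimnames = list(o1$entities$id, o2$entities$id))
  if (nrow(A)) {
    unknown1 <- setdiff(A$e1, rownames(M))
    unknown2 <- setdiff(A$e2, colnames(M))
    if (length(unknown1) || length(unknown2)) {
      stop("alignment references entity outside the ontology pair: ",
           c(unknown1, unknown2)[1], call. = FALSE)
    }
    M[cbind(A$e1, A$e2)] <- 1
  }
  M
}

#' Approximated recall of an alignment
#'
#' Reference-free completeness proxy: the alignment size normalized by the
#' largest possible 1:1 alignment, `|A| / min(|O1|, |O2|)`, clamped to
#' `[0, 1]`. An empty alignment (or an empty ontology pair) scores 0.
#'
#' @param A an [alignment][new_alignment].
#' @param o1,o2 the aligned [ontology][new_ontology] objects.
#' @return value in `[0, 1]`.
#' @export
recall_prime <- function(A, o1, o2) {
  denom <- min(ontology_size(o1), ontology_size(o2))
  if (denom == 0L) return(0)
  min(1, nrow(A) / denom)
}

#' Approximated precision of an alignment
#'
#' Reference-free correctness proxy: the mean confidence of the
#' correspondences. An empty alignment scores 0 by convention.
#'
#' @param A an [alignment][new_alignment].
#' @return value in `[0, 1]`.
#' @export
precision_prime <- function(A) {
  if (nrow(A) == 0L) return(0)
  mean(A$conf)
}

#' Approximated f-measure (the evolutionary fitness)
#'
#' Harmonic mean of [recall_prime()] and [precision_prime()]; 0 when both are
#' 0. Maximizing this quantity over 0-1 aligning matrices is the optimization
#' model the search engine solves.
#'
#' @inheritParams recall_prime
#' @return value in `[0, 1]`.
#' @export
f_measure_prime <- function(A, o1, o2) {
  harmonic_mean(precision_prime(A), recall_prime(A, o1, o2))
}

harmonic_mean <- function(p, r) {
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Classical precision/recall/f-measure against a reference alignment
#'
#' Correspondences are intersected by `(e1, e2)` identity. Precision is
#' `|A & ref| / |A|`, recall is `|A & ref| / |ref|`; an empty `A` scores 0 on
#' all three metrics.
#'
#' @param A evaluated [alignment][new_alignment].
#' @param ref non-empty reference alignment over the same ontology pair.
#' @return named list with `precision`, `recall`, `f_measure`.
#' @export
evaluate_against_reference <- function(A, ref) {
  if (nrow(ref) == 0L) {
    stop("reference alignment is empty; recall undefined", call. = FALSE)
  }
  key <- function(x) paste(x$e1, x$e2, sep = "\r")
  hits <- sum(key(A) %in% key(ref))
  precision <- if (nrow(A) == 0L) 0 else hits / nrow(A)
  recall <- hits / nrow(ref)
  list(precision = precision, recall = recall,
       f_measure = harmonic_mean(precision, recall))
}

#' Greedy 1:1 cardinality repair of an aligning matrix
#'
#' Enforces single cardinality (at most one correspondence per entity): the
#' 1-cells are visited in descending confidence (ties broken by row then
#' column index) and a cell is kept only when both its row and its column are
#' still unused. The kept cells are always a subset of the input cells.
#'
#' @param M 0-1 matrix.
#' @param sims numeric matrix of confidences, same shape.
#' @return repaired 0-1 matrix with at most one 1 per row and per column.
#' @export
enforce_single_cardinality <- function(M, sims) {
  stopifnot(is.matrix(M))
  if (!identical(dim(M), dim(sims))) {
    stop("`M` and `sims` must have the same shape", call. = FALSE)
  }
  ones <- which(M == 1)
  if (length(ones) <= 1L) return(M)
  rows <- ((ones - 1L) %% nrow(M)) + 1L
  cols <- ((ones - 1L) %/% nrow(M)) + 1L
  ord <- order(-sims[ones], rows, cols)
  out <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  row_used <- logical(nrow(M))
  col_used <- logical(ncol(M))
  for (k in ord) {
    i <- rows[k]
    j <- cols[k]
    if (!row_used[i] && !col_used[j]) {
      out[i, j] <- 1
      row_used[i] <- TRUE
      col_used[j] <- TRUE
    }
  }
  out
}

#' Write an alignment in the OAEI Alignment format
#'
#' Emits RDF/XML in the Alignment format used by the Ontology Alignment
#' Evaluation Initiative (one `Cell` per correspondence with `entity1`,
#' `entity2`, `relation` `"="` and `measure`), plus a CSV sidecar
#' (`source_id,target_id,conf`) next to it. Confidences are serialized with
#' full precision.
#'
#' @param A an [alignment][new_alignment].
#' @param path output path for the RDF file; the sidecar replaces the
#'   extension with `.csv`.
#' @param csv_sidecar write the CSV sidecar too (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(A, path, csv_sidecar = TRUE) {
  align_ns <- "http://knowledgeweb.semanticweb.org/heterogeneity/alignment"
  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    "xmlns:xsd" = "http://www.w3.org/2001/XMLSchema#",
    "xmlns" = paste0(align_ns, "#")
  )
  al <- xml2::xml_add_child(doc, "Alignment")
  xml2::xml_add_child(al, "xml", "yes")
  xml2::xml_add_child(al, "level", "0")
  xml2::xml_add_child(al, "type", "11")
  xml2::xml_add_child(al, "onto1", attr(A, "source") %||% "O1")
  xml2::xml_add_child(al, "onto2", attr(A, "target") %||% "O2")
  for (k in seq_len(nrow(A))) {
    map <- xml2::xml_add_child(al, "map")
    cell <- xml2::xml_add_child(map, "Cell")
    e1 <- xml2::xml_add_child(cell, "entity1")
    xml2::xml_set_attr(e1, "rdf:resource", A$e1[k])
    e2 <- xml2::xml_add_child(cell, "entity2")
    xml2::xml_set_attr(e2, "rdf:resource", A$e2[k])
    xml2::xml_add_child(cell, "relation", "=")
    meas <- xml2::xml_add_child(cell, "measure",
                                sprintf("%.10f", A$conf[k]))
    xml2::xml_set_attr(meas, "rdf:datatype",
                       "http://www.w3.org/2001/XMLSchema#float")
  }
  xml2::write_xml(doc, path)
  if (csv_sidecar) {
    csv_path <- paste0(tools::file_path_sans_ext(path), ".csv")
    write_alignment_csv(A, csv_path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_alignment
#' @export
write_alignment_csv <- function(A, path) {
  df <- data.frame(source_id = A$e1, target_id = A$e2,
                   conf = sprintf("%.10f", A$conf), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an alignment file
#'
#' Reads either the OAEI Alignment RDF format (as written by
#' [write_alignment()]) or the CSV sidecar format, inferred from the file
#' extension.
#'
#' @param path path to an `.rdf`/`.xml` Alignment file or a `.csv` sidecar.
#' @return an [alignment][new_alignment].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path,
                               call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(new_alignment(data.frame(e1 = df$source_id, e2 = df$target_id,
                                    conf = as.numeric(df$conf))))
  }
  doc <- xml2::read_xml(path)
  ns <- c(
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    al = "http://knowledgeweb.semanticweb.org/heterogeneity/alignment#"
  )
  cells <- xml2::xml_find_all(doc, "//al:Cell", ns)
  if (!length(cells)) {
    onto <- xml2::xml_find_first(doc, "//al:Alignment/al:onto1", ns)
    return(new_alignment(
      source = if (inherits(onto, "xml_missing")) "O1" else xml2::xml_text(onto)
    ))
  }
  e1 <- vapply(cells, function(x) {
    xml2::xml_attr(xml2::xml_find_first(x, "./al:entity1", ns), "resource")
  }, character(1))
  e2 <- vapply(cells, function(x) {
    xml2::xml_attr(xml2::xml_find_first(x, "./al:entity2", ns), "resource")
  }, character(1))
  conf <- vapply(cells, function(x) {
    as.numeric(xml2::xml_text(xml2::xml_find_first(x, "./al:measure", ns)))
  }, numeric(1))
  onto1 <- xml2::xml_find_first(doc, "//al:Alignment/al:onto1", ns)
  onto2 <- xml2::xml_find_first(doc, "//al:Alignment/al:onto2", ns)
  new_alignment(
    data.frame(e1 = e1, e2 = e2, conf = conf, stringsAsFactors = FALSE),
    source = if (inherits(onto1, "xml_missing")) "O1" else xml2::xml_text(onto1),
    target = if (inherits(onto2, "xml_missing")) "O2" else xml2::xml_text(onto2)
  )
}
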