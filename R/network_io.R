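# Readers/writers for typed regulatory networks: SIF (relation as the
# interaction token), GraphML (via igraph, keeps node classes explicitly),
# and a 3-column edge TSV. SIF and TSV carry classes implicitly through the
# relation kinds; GraphML round-trips isolated nodes and dual flags too.

#' Write a regulatory network to file
#'
#' @param network a [regulatory_network()].
#' @param path output file path.
#' @param format one of `"SIF"`, `"GraphML"`, `"edge-TSV"`.
#' @export
write_network <- function(network, path, format = c("SIF", "GraphML", "edge-TSV")) {
  if (length(format) == 1L && !format %in% c("SIF", "GraphML", "edge-TSV"))
    stop("unknown network format: ", format, call. = FALSE)
  format <- match.arg(format)
  e <- network$edges
  if (format == "SIF") {
    lines <- if (nrow(e)) paste(e$source, e$relation, e$target, sep = "\t") else character(0)
    writeLines(lines, path)
  } else if (format == "edge-TSV") {
    writeLines(c("source\trelation\ttarget",
                 if (nrow(e)) paste(e$source, e$relation, e$target, sep = "\t")), path)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("source", "target")], directed = TRUE,
      vertices = network$nodes[, c("id", "class", "dual")])
    if (nrow(e)) igraph::E(g)$relation <- e$relation
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

infer_network_from_typed_edges <- function(edges) {
  roles <- list()
  add_role <- function(ids, class) {
    for (id in unique(ids)) roles[[id]] <<- union(roles[[id]], class)
  }
  for (rel in unique(edges$relation)) {
    cls <- relation_classes(rel)
    sel <- edges$relation == rel
    add_role(edges$source[sel], cls[["source"]])
    add_role(edges$target[sel], cls[["target"]])
  }
  ids <- names(roles)
  nodes <- do.call(rbind, lapply(ids, function(id) {
    data.frame(id = id, class = roles[[id]], stringsAsFactors = FALSE)
  }))
  regulatory_network(nodes, edges)
}

#' Read a regulatory network from file
#'
#' Inverse of [write_network()]. For SIF and edge-TSV input the node classes
#' are inferred from the relation kinds each node participates in (a node
#' seen in both gene and TF roles becomes dual); GraphML input restores the
#' stored classes directly.
#'
#' @param path input file path.
#' @param format one of `"SIF"`, `"GraphML"`, `"edge-TSV"`.
#' @return A [regulatory_network()].
#' @export
read_network <- function(path, format = c("SIF", "GraphML", "edge-TSV")) {
  if (length(format) == 1L && !format %in% c("SIF", "GraphML", "edge-TSV"))
    stop("unknown network format: ", format, call. = FALSE)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "GraphML") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(g)$name, class = igraph::V(g)$class,
                        stringsAsFactors = FALSE)
    dual <- igraph::V(g)$dual
    if (!is.null(dual) && any(as.logical(dual))) {
      extra <- data.frame(id = nodes$id[as.logical(dual)], class = "tf")
      nodes <- rbind(nodes, extra)
    }
    if (igraph::ecount(g) > 0L) {
      ends <- igraph::as_edgelist(g)
      edges <- data.frame(source = ends[, 1L], target = ends[, 2L],
                          relation = igraph::E(g)$relation, stringsAsFactors = FALSE)
    } else edges <- NULL
    return(regulatory_network(nodes, edges))
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "edge-TSV") lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(regulatory_network(data.frame(id = character(0), class = character(0)), NULL))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed line in ", path, call. = FALSE)
  m <- do.call(rbind, parts)
  edges <- data.frame(source = m[, 1L], relation = m[, 2L], target = m[, 3L],
                      stringsAsFactors = FALSE)
  bad <- setdiff(unique(edges$relation), RELATIONS)
  if (length(bad)) stop("unknown relation(s) in ", path, ": ",
                        paste(bad, collapse = ", "), call. = FALSE)
  infer_network_from_typed_edges(edges)
}
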