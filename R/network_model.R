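# regulatory_network: merged node/edge graph with per-class node typing,
# per-relation edge typing, and per-edge provenance (contributing merged-FFL
# keys). Degrees and communities are computed on the undirected simple
# projection, matching how the analyses treat the graph.

edge_key <- function(source, target, relation) {
  paste(source, relation, target, sep = "\r")
}

#' Construct a typed regulatory network
#'
#' @param nodes data frame with columns `id` and `class`
#'   (`gene`/`mirna`/`tf`); a node listed under both `gene` and `tf`
#'   collapses to one row with `dual = TRUE` and class `gene`.
#' @param edges data frame with columns `source`, `target`, `relation`.
#' @param provenance optional named list: edge key -> character vector of
#'   contributing merged-FFL keys (`"tf|mirna|class|arity"`).
#' @return An object of class `regulatory_network`.
#' @export
regulatory_network <- function(nodes, edges, provenance = NULL) {
  stopifnot(all(c("id", "class") %in% names(nodes)))
  stopifnot(all(nodes$class %in% c("gene", "mirna", "tf")))
  nodes <- unique(nodes[, c("id", "class")])
  dup <- nodes$id[duplicated(nodes$id)]
  dual <- unique(nodes$id[nodes$id %in% dup])
  if (length(dual)) {
    bad <- nodes$id %in% dual & nodes$class == "mirna"
    if (any(bad)) stop("a node cannot be both a miRNA and another class", call. = FALSE)
    # dual gene/TF nodes are represented once, under the gene role
    nodes <- nodes[!(nodes$id %in% dual & nodes$class == "tf"), , drop = FALSE]
  }
  nodes$dual <- nodes$id %in% dual
  nodes <- nodes[order(nodes$class, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(0), target = character(0),
                        relation = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- canonicalize_edges(cbind(edges[, c("source", "target", "relation")],
                                      score = NA_real_))
    edges$score <- NULL
    miss <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    if (length(miss))
      stop("edge endpoints missing from node table: ",
           paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges,
                 provenance = provenance %||% list()),
            class = "regulatory_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) print(table(x$nodes$class))
  if (nrow(x$edges)) print(table(x$edges$relation))
  invisible(x)
}

#' Node class lookup for a network
#' @keywords internal
network_class_of <- function(network) {
  setNames(network$nodes$class, network$nodes$id)
}

#' Undirected simple igraph projection of a regulatory network
#'
#' Edge direction is ignored and parallel relations between the same
#' endpoint pair collapse to one adjacency, which is how degrees, hubs,
#' communities and components are defined here.
#'
#' @param network a [regulatory_network()].
#' @param collapse collapse parallel relations to one adjacency (default
#'   TRUE); set FALSE to keep relation multiplicity.
#' @return an igraph object with vertex attribute `class`.
#' @export
as_undirected_graph <- function(network, collapse = TRUE) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target")],
    directed = FALSE,
    vertices = network$nodes[, c("id", "class")])
  if (collapse) g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g
}
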