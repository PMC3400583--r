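# Topology analyses of the merged regulatory network: construction from
# merged FFLs with per-edge provenance, degree summaries on the undirected
# simple projection, top-quantile hub calling with a median guard, composite
# and seed-gene subnetworks, TF<->miRNA feedback loops, k-clique-percolation
# communities, and node ablation.

#' Build the merged regulatory network from merged FFLs
#'
#' Expands every merged FFL into its constituent regulatory edges and takes
#' the deduplicated union. When the merged set carries member-edge detail
#' (the output of [merge_ffls()] does), those exact edges are used; merged
#' sets imported from a targets-only table fall back to the canonical
#' template expansion (for 4-node records: the first gene of each pair takes
#' the TF-required slot).
#'
#' @param merged a `merged_ffl_set` (either arity or both, see
#'   [bind_merged_ffls()]).
#' @return A [regulatory_network()] with per-edge provenance: the set of
#'   contributing merged-FFL keys (`"tf|mirna|class|arity"`).
#' @export
build_network <- function(merged) {
  edges <- attr(merged, "member_edges")
  if (is.null(edges)) edges <- template_member_edges(merged)
  if (is.null(edges) || nrow(edges) == 0L) {
    return(regulatory_network(data.frame(id = character(0), class = character(0)), NULL))
  }
  gg <- edges$relation == "gene-gene"
  if (any(gg)) {
    a <- pmin(edges$source[gg], edges$target[gg])
    b <- pmax(edges$source[gg], edges$target[gg])
    edges$source[gg] <- a; edges$target[gg] <- b
  }
  key <- edge_key(edges$source, edges$target, edges$relation)
  provenance <- lapply(split(edges$ffl_key, key), unique)
  uniq <- edges[!duplicated(key), c("source", "target", "relation"), drop = FALSE]
  nodes <- node_frame_from_edges(uniq)
  regulatory_network(nodes, uniq, provenance = provenance)
}

node_frame_from_edges <- function(edges) {
  rows <- list()
  for (rel in unique(edges$relation)) {
    cls <- relation_classes(rel)
    sel <- edges$relation == rel
    rows[[length(rows) + 1L]] <- data.frame(id = edges$source[sel], class = cls[["source"]])
    rows[[length(rows) + 1L]] <- data.frame(id = edges$target[sel], class = cls[["target"]])
  }
  unique(do.call(rbind, rows))
}

# fallback expansion for targets-only merged tables (import mode): required
# edges only, with the first gene of a 4-node pair in the TF slot
template_member_edges <- function(merged) {
  if (nrow(merged) == 0L) return(NULL)
  flat <- flatten_merged_ffls(merged)
  rows <- lapply(seq_len(nrow(flat)), function(i) {
    f <- flat[i, ]
    key <- paste(f$tf, f$mirna, f$ffl_class, f$arity, sep = "|")
    reg <- switch(f$ffl_class,
      "TF-FFL" = data.frame(source = f$tf, target = f$mirna, relation = "TF-miRNA"),
      "miRNA-FFL" = data.frame(source = f$mirna, target = f$tf, relation = "miRNA-TF"),
      "composite-FFL" = data.frame(source = c(f$tf, f$mirna), target = c(f$mirna, f$tf),
                                   relation = c("TF-miRNA", "miRNA-TF")))
    tgt <- if (f$arity == "3-node") {
      data.frame(source = c(f$tf, f$mirna), target = rep(f$target, 2L),
                 relation = c("TF-gene", "miRNA-gene"))
    } else {
      gs <- strsplit(f$target, "|", fixed = TRUE)[[1L]]
      data.frame(source = c(gs[1L], f$tf, f$mirna), target = c(gs[2L], gs[1L], gs[2L]),
                 relation = c("gene-gene", "TF-gene", "miRNA-gene"))
    }
    e <- rbind(reg, tgt); e$ffl_key <- key; e
  })
  do.call(rbind, rows)
}

#' Per-class degree summary on the undirected simple projection
#'
#' Degrees ignore edge direction and collapse parallel relations between the
#' same endpoints into one adjacency (set `collapse = FALSE` for
#' relation-multiplicity counting). Dual gene/TF nodes are counted once,
#' under the gene role.
#'
#' @param network a [regulatory_network()].
#' @param collapse see [as_undirected_graph()].
#' @return list with `degrees` (named vector), `by_class` (data frame of
#'   class, n, min, max, mean) and `distribution` (data frame of class,
#'   degree, fraction of that class's nodes).
#' @export
degree_summary <- function(network, collapse = TRUE) {
  if (nrow(network$nodes) == 0L)
    return(list(degrees = numeric(0),
                by_class = data.frame(class = character(0), n = integer(0),
                                      min = numeric(0), max = numeric(0), mean = numeric(0)),
                distribution = data.frame(class = character(0), degree = integer(0),
                                          fraction = numeric(0))))
  g <- as_undirected_graph(network, collapse = collapse)
  deg <- igraph::degree(g)
  cls <- setNames(igraph::V(g)$class, igraph::V(g)$name)
  by_class <- do.call(rbind, lapply(sort(unique(cls)), function(cl) {
    d <- deg[cls == cl]
    data.frame(class = cl, n = length(d), min = min(d), max = max(d),
               mean = mean(d), stringsAsFactors = FALSE)
  }))
  distribution <- do.call(rbind, lapply(sort(unique(cls)), function(cl) {
    d <- deg[cls == cl]
    tab <- table(d) / length(d)
    data.frame(class = cl, degree = as.integer(names(tab)),
               fraction = as.numeric(tab), stringsAsFactors = FALSE)
  }))
  list(degrees = deg, by_class = by_class, distribution = distribution)
}

#' Per-class hub detection by top-degree quantile
#'
#' For each node class with at least 5 members, the cutoff is the smallest
#' degree among the top ceiling(quantile * n) nodes by degree; hubs are the
#' nodes with degree >= cutoff whose degree also strictly exceeds the class
#' median (so degenerate all-equal classes yield no hubs).
#'
#' @param network a [regulatory_network()].
#' @param quantile_ fraction of each class treated as the top tier
#'   (default 0.20).
#' @return data frame: `class`, `cutoff`, `quantile`, `hubs`
#'   (semicolon-joined ids); classes with fewer than 5 nodes are skipped
#'   with a warning.
#' @export
find_hubs <- function(network, quantile_ = 0.20) {
  stopifnot(quantile_ > 0, quantile_ < 1)
  empty <- data.frame(class = character(0), cutoff = numeric(0),
                      quantile = numeric(0), hubs = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(network$nodes) == 0L) return(empty)
  ds <- degree_summary(network)
  deg <- ds$degrees
  cls <- setNames(network$nodes$class, network$nodes$id)[names(deg)]
  out <- list()
  for (cl in sort(unique(cls))) {
    d <- sort(deg[cls == cl], decreasing = TRUE)
    if (length(d) < 5L) {
      warning("class '", cl, "' has fewer than 5 nodes; skipped", call. = FALSE)
      next
    }
    cutoff <- d[ceiling(quantile_ * length(d))]
    med <- median(d)
    hubs <- names(d)[d >= cutoff & d > med]
    out[[length(out) + 1L]] <- data.frame(
      class = cl, cutoff = as.numeric(cutoff), quantile = quantile_,
      hubs = paste(hubs, collapse = ";"), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Subnetwork of composite-class FFLs only
#'
#' @param merged a `merged_ffl_set`.
#' @return [build_network()] restricted to `ffl_class == "composite-FFL"`;
#'   its edge set is a subset of the full network's.
#' @export
composite_subnetwork <- function(merged) {
  build_network(subset_merged(merged, merged$ffl_class == "composite-FFL"))
}

#' Subnetwork seeded by a node set
#'
#' Builds the network over exactly the merged FFLs whose TF, miRNA, or any
#' target gene intersects the seed set (for 4-node records either gene of a
#' target pair counts).
#'
#' @param merged a `merged_ffl_set`.
#' @param seeds non-empty character vector of node identifiers.
#' @return A [regulatory_network()]; empty when no FFL touches the seeds.
#' @export
seeded_subnetwork <- function(merged, seeds) {
  if (length(seeds) == 0L) stop("seeds must be non-empty", call. = FALSE)
  touch <- vapply(seq_len(nrow(merged)), function(i) {
    tgt <- unlist(strsplit(strsplit(merged$targets[i], ";", fixed = TRUE)[[1L]],
                           "|", fixed = TRUE))
    any(c(merged$tf[i], merged$mirna[i], tgt) %in% seeds)
  }, logical(1))
  build_network(subset_merged(merged, touch))
}

subset_merged <- function(merged, keep) {
  out <- merged[keep, , drop = FALSE]
  edges <- attr(merged, "member_edges")
  if (!is.null(edges) && nrow(out)) {
    keys <- paste(out$tf, out$mirna, out$ffl_class, out$arity, sep = "|")
    edges <- edges[edges$ffl_key %in% keys, , drop = FALSE]
  } else if (!is.null(edges)) {
    edges <- edges[0L, , drop = FALSE]
  }
  attr(out, "member_edges") <- edges
  class(out) <- c("merged_ffl_set", "data.frame")
  out
}

#' TF<->miRNA feedback loops
#'
#' Pairs connected by reciprocal regulation (both TF->miRNA and miRNA->TF
#' edges) - the defining feature of composite FFLs.
#'
#' @param x a [regulatory_network()] or [edge_store()].
#' @return data frame `tf`, `mirna`, deduplicated and sorted.
#' @export
feedback_loops <- function(x) {
  stopifnot(inherits(x, "edge_store") || inherits(x, "regulatory_network"))
  edges <- x$edges
  t2m <- edges[edges$relation == "TF-miRNA", , drop = FALSE]
  m2t <- edges[edges$relation == "miRNA-TF", , drop = FALSE]
  keys <- intersect(paste(t2m$source, t2m$target, sep = "\r"),
                    paste(m2t$target, m2t$source, sep = "\r"))
  if (length(keys) == 0L)
    return(data.frame(tf = character(0), mirna = character(0), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(sort(keys), "\r", fixed = TRUE))
  data.frame(tf = parts[, 1L], mirna = parts[, 2L], stringsAsFactors = FALSE)
}

#' k-clique-percolation communities
#'
#' Communities are the connected components of the k-clique adjacency graph:
#' two k-cliques are adjacent iff they share k-1 nodes, and a community is
#' the node union of one component's cliques. Runs on the undirected simple
#' projection; a node may belong to several communities. With k = 2 this
#' reduces to the ordinary connected components.
#'
#' @param network a [regulatory_network()].
#' @param k clique size, >= 2 (default 3).
#' @return list of character vectors (sorted community memberships), ordered
#'   by decreasing size.
#' @export
k_clique_communities <- function(network, k = 3L) {
  stopifnot(k >= 2L)
  g <- as_undirected_graph(network)
  cl <- igraph::cliques(g, min = k, max = k)
  if (length(cl) == 0L) return(list())
  members <- lapply(cl, function(c_) sort(igraph::V(g)$name[as.integer(c_)]))
  nc <- length(members)
  adj_i <- integer(0); adj_j <- integer(0)
  if (nc > 1L) {
    for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
      if (length(intersect(members[[i]], members[[j]])) == k - 1L) {
        adj_i <- c(adj_i, i); adj_j <- c(adj_j, j)
      }
    }
  }
  cg <- igraph::graph_from_data_frame(data.frame(from = adj_i, to = adj_j),
                                      directed = FALSE,
                                      vertices = data.frame(name = seq_len(nc)))
  comp <- igraph::components(cg)$membership
  comms <- unname(lapply(split(seq_len(nc), comp), function(idx) {
    sort(unique(unlist(members[idx])))
  }))
  comms[order(-lengths(comms),
              vapply(comms, paste, character(1), collapse = "|"))]
}

#' Remove nodes and report connectivity change
#'
#' @param network a [regulatory_network()].
#' @param removed character vector of node ids to delete (with incident
#'   edges).
#' @return the reduced [regulatory_network()], with attribute `components`:
#'   a named integer vector `c(before=, after=)` of connected-component
#'   counts on the undirected projection.
#' @export
ablate_nodes <- function(network, removed) {
  before <- if (nrow(network$nodes)) igraph::components(as_undirected_graph(network))$no else 0L
  keep_nodes <- !(network$nodes$id %in% removed)
  nodes <- network$nodes[keep_nodes, , drop = FALSE]
  # dual nodes occupy one row under the gene class; restore the tf row so
  # the constructor can rebuild the dual flag
  if (any(nodes$dual)) {
    nodes <- rbind(nodes[, c("id", "class")],
                   data.frame(id = nodes$id[nodes$dual], class = "tf"))
  } else nodes <- nodes[, c("id", "class")]
  keep_edges <- !(network$edges$source %in% removed | network$edges$target %in% removed)
  edges <- network$edges[keep_edges, , drop = FALSE]
  prov <- network$provenance[edge_key(edges$source, edges$target, edges$relation)]
  out <- regulatory_network(nodes, edges, provenance = prov)
  after <- if (nrow(out$nodes)) igraph::components(as_undirected_graph(out))$no else 0L
  attr(out, "components") <- c(before = before, after = after)
  out
}
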