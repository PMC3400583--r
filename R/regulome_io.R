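#' @importFrom stats phyper dhyper p.adjust quantile median rnorm runif t.test setNames
#' @importFrom utils read.table write.table head combn
NULL

# The five regulatory relation kinds and the node classes they connect.
RELATIONS <- c("TF-gene", "TF-miRNA", "miRNA-gene", "miRNA-TF", "gene-gene")

relation_classes <- function(relation) {
  switch(relation,
    "TF-gene"    = c(source = "tf",    target = "gene"),
    "TF-miRNA"   = c(source = "tf",    target = "mirna"),
    "miRNA-gene" = c(source = "mirna", target = "gene"),
    "miRNA-TF"   = c(source = "mirna", target = "tf"),
    "gene-gene"  = c(source = "gene",  target = "gene"),
    stop("unknown relation: ", relation, call. = FALSE)
  )
}

#' Node catalog over the three regulatory node classes
#'
#' Holds the three node universes of the analysis: candidate genes, mature
#' miRNAs, and transcription factors. A node may legitimately appear in both
#' the gene and TF sets (TF genes are themselves regulated at their
#' promoters); class-membership checks treat such nodes as dual-role.
#'
#' @param genes,mirnas,tfs character vectors of identifiers. Whitespace is
#'   trimmed and duplicates are removed; empty strings are rejected.
#' @return An object of class `node_catalog` with elements `genes`,
#'   `mirnas`, `tfs` (sorted character vectors).
#' @export
node_catalog <- function(genes, mirnas, tfs) {
  clean <- function(x, what) {
    x <- trimws(as.character(x))
    x <- x[nzchar(x)]
    if (length(x) == 0L) stop("empty ", what, " identifier set", call. = FALSE)
    sort(unique(x))
  }
  structure(
    list(genes = clean(genes, "gene"),
         mirnas = clean(mirnas, "miRNA"),
         tfs = clean(tfs, "TF")),
    class = "node_catalog"
  )
}

#' @export
print.node_catalog <- function(x, ...) {
  dual <- intersect(x$genes, x$tfs)
  cat(sprintf("node_catalog: %d genes, %d miRNAs, %d TFs (%d dual gene/TF)\n",
              length(x$genes), length(x$mirnas), length(x$tfs), length(dual)))
  invisible(x)
}

#' Membership test honouring dual roles
#'
#' @param catalog a [node_catalog()].
#' @param ids character vector of identifiers.
#' @param class one of `"gene"`, `"mirna"`, `"tf"`.
#' @return logical vector: is each id a member of that class?
#' @export
in_class <- function(catalog, ids, class) {
  pool <- switch(class,
    gene = catalog$genes, mirna = catalog$mirnas, tf = catalog$tfs,
    stop("unknown node class: ", class, call. = FALSE))
  ids %in% pool
}

#' Read a node catalog from three plain-text identifier lists
#'
#' Each file holds one identifier per line; blank lines and lines starting
#' with `#` are ignored. Identifiers are trimmed and deduplicated.
#'
#' @param genes_path,mirnas_path,tfs_path file paths.
#' @return A [node_catalog()].
#' @export
load_node_catalog <- function(genes_path, mirnas_path, tfs_path) {
  read_ids <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    x <- readLines(path, warn = FALSE)
    x <- trimws(x)
    x <- x[nzchar(x) & !startsWith(x, "#")]
    if (length(x) == 0L) stop("no identifiers in file: ", path, call. = FALSE)
    x
  }
  cat_ <- node_catalog(read_ids(genes_path), read_ids(mirnas_path), read_ids(tfs_path))
  message(sprintf("loaded catalog: %d genes, %d miRNAs, %d TFs",
                  length(cat_$genes), length(cat_$mirnas), length(cat_$tfs)))
  cat_
}

empty_edge_frame <- function() {
  data.frame(source = character(0), target = character(0),
             relation = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0L) return(empty_edge_frame())
  gg <- edges$relation == "gene-gene"
  if (any(gg)) {
    a <- pmin(edges$source[gg], edges$target[gg])
    b <- pmax(edges$source[gg], edges$target[gg])
    edges$source[gg] <- a
    edges$target[gg] <- b
  }
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  key <- paste(edges$source, edges$target, edges$relation, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$relation, edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Typed, deduplicated store of regulatory edges
#'
#' Container over the five relation kinds. Gene-gene edges are undirected
#' and stored with their endpoints in canonical (lexicographic) order;
#' duplicate (source, target, relation) triples collapse to one edge;
#' self-edges are dropped. Every endpoint must belong to the node class its
#' relation requires (dual gene/TF nodes satisfy either role).
#'
#' @param edges data frame with columns `source`, `target`, `relation` and
#'   optionally `score` (`NA` when unknown).
#' @param catalog a [node_catalog()].
#' @return An object of class `edge_store` with elements `edges`, `catalog`.
#' @export
edge_store <- function(edges, catalog) {
  stopifnot(inherits(catalog, "node_catalog"))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- empty_edge_frame()
  } else {
    if (!all(c("source", "target", "relation") %in% names(edges)))
      stop("edges need columns source, target, relation", call. = FALSE)
    if (is.null(edges$score)) edges$score <- NA_real_
    edges <- edges[, c("source", "target", "relation"), drop = FALSE] |>
      cbind(score = as.numeric(edges$score))
    bad <- setdiff(unique(edges$relation), RELATIONS)
    if (length(bad)) stop("unknown relation(s): ", paste(bad, collapse = ", "), call. = FALSE)
    edges <- canonicalize_edges(edges)
    for (rel in unique(edges$relation)) {
      cls <- relation_classes(rel)
      sel <- edges$relation == rel
      ok <- in_class(catalog, edges$source[sel], cls[["source"]]) &
            in_class(catalog, edges$target[sel], cls[["target"]])
      if (!all(ok))
        stop(sprintf("%d %s edge(s) with endpoints outside the required catalog classes",
                     sum(!ok), rel), call. = FALSE)
    }
  }
  structure(list(edges = edges, catalog = catalog), class = "edge_store")
}

#' @export
print.edge_store <- function(x, ...) {
  cat(sprintf("edge_store: %d edges\n", nrow(x$edges)))
  if (nrow(x$edges)) print(table(x$edges$relation))
  invisible(x)
}

#' Select the edges of one relation kind
#' @param store an [edge_store()].
#' @param relation one of the five relation kinds.
#' @return data frame of edges.
#' @export
edges_of <- function(store, relation) {
  stopifnot(relation %in% RELATIONS)
  store$edges[store$edges$relation == relation, , drop = FALSE]
}

#' Test presence of a directed edge
#' @keywords internal
has_edge <- function(store, source, target, relation) {
  e <- edges_of(store, relation)
  any(e$source == source & e$target == target)
}

#' Load an edge table from TSV
#'
#' Reads a 2-3 column TSV (`source`, `target`, optional `score`; header
#' optional, detected by a non-numeric third field named `score` or by the
#' literal header `source`). Rows whose endpoints fall outside the catalog
#' classes required by `relation` are dropped with a message in non-strict
#' mode, and are an error (with the offending row number) in strict mode.
#'
#' @param path TSV file path.
#' @param relation the relation kind to assign every row.
#' @param catalog a [node_catalog()].
#' @param strict error on out-of-catalog endpoints instead of dropping.
#' @return An [edge_store()].
#' @export
load_edge_table <- function(path, relation, catalog, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(relation %in% RELATIONS)
  first <- readLines(path, n = 1L, warn = FALSE)
  header <- length(first) == 1L && grepl("^source\t", first)
  tab <- read.table(path, sep = "\t", header = header, stringsAsFactors = FALSE,
                    colClasses = "character", fill = FALSE, quote = "")
  if (ncol(tab) < 2L || ncol(tab) > 3L)
    stop("edge table must have 2 or 3 columns: ", path, call. = FALSE)
  names(tab)[1:2] <- c("source", "target")
  score <- if (ncol(tab) >= 3L) suppressWarnings(as.numeric(tab[[3L]])) else NA_real_
  edges <- data.frame(source = trimws(tab$source), target = trimws(tab$target),
                      relation = relation, score = score, stringsAsFactors = FALSE)
  cls <- relation_classes(relation)
  ok <- in_class(catalog, edges$source, cls[["source"]]) &
        in_class(catalog, edges$target, cls[["target"]])
  if (!all(ok)) {
    if (strict)
      stop(sprintf("row %d of %s has an endpoint outside the catalog",
                   which(!ok)[1L] + header, path), call. = FALSE)
    message(sprintf("dropped %d/%d out-of-catalog rows from %s",
                    sum(!ok), nrow(edges), path))
    edges <- edges[ok, , drop = FALSE]
  }
  edge_store(edges, catalog)
}

#' Parse a TargetScan-style prediction table
#'
#' Expects a TSV with columns `mirna`, `target`, `total_context_score`, and
#' `species` (comma-joined species codes marking where the site is present).
#'
#' @param path TSV path with a header row.
#' @return data frame with columns `mirna`, `target`,
#'   `total_context_score` (numeric) and `species` (list of character).
#' @export
read_target_predictions <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, quote = "")
  need <- c("mirna", "target", "total_context_score", "species")
  if (!all(need %in% names(tab)))
    stop("prediction table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  tab$total_context_score <- as.numeric(tab$total_context_score)
  if (any(!is.finite(tab$total_context_score)))
    stop("non-finite total_context_score in ", path, call. = FALSE)
  tab$species <- strsplit(tab$species, ",", fixed = TRUE)
  tab
}

#' Filter miRNA target predictions by conservation and context score
#'
#' Keeps predictions whose target site is present in every required species
#' and whose total context score indicates at least the requested repression
#' strength. Context scores are negative with more-negative meaning stronger
#' predicted repression, so the default comparator keeps scores less than or
#' equal to the cutoff (magnitude reading, boundary inclusive); the literal
#' `>=` direction is available via `comparator = "ge"`.
#'
#' Kept records become `miRNA-gene` or `miRNA-TF` edges according to the
#' target's class in the catalog (a dual gene/TF target yields both).
#'
#' @param records data frame as returned by [read_target_predictions()].
#' @param catalog a [node_catalog()].
#' @param required_species character vector of species codes (default the
#'   four-way human/mouse/rat/dog conservation set).
#' @param score_cutoff total context score cutoff (default -0.30).
#' @param comparator `"le"` (default; keep score <= cutoff) or `"ge"`.
#' @param known_species declared species universe used to validate codes.
#' @return An [edge_store()] of miRNA-gene / miRNA-TF edges, scored by the
#'   total context score.
#' @export
filter_target_predictions <- function(records, catalog,
                                      required_species = c("hsa", "mmu", "rno", "cfa"),
                                      score_cutoff = -0.30,
                                      comparator = c("le", "ge"),
                                      known_species = c("hsa", "mmu", "rno", "cfa")) {
  comparator <- match.arg(comparator)
  if (length(required_species) == 0L)
    stop("required_species must be non-empty", call. = FALSE)
  seen <- unique(c(required_species, unlist(records$species)))
  bad <- setdiff(seen, known_species)
  if (length(bad))
    stop("unknown species code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  conserved <- vapply(records$species, function(s) all(required_species %in% s), logical(1))
  strong <- if (comparator == "le") records$total_context_score <= score_cutoff
            else records$total_context_score >= score_cutoff
  kept <- records[conserved & strong, , drop = FALSE]
  message(sprintf("target-prediction filter kept %d/%d records", nrow(kept), nrow(records)))
  rows <- list(empty_edge_frame())
  if (nrow(kept)) {
    as_gene <- in_class(catalog, kept$target, "gene") & kept$mirna %in% catalog$mirnas
    as_tf <- in_class(catalog, kept$target, "tf") & kept$mirna %in% catalog$mirnas
    if (any(as_gene))
      rows <- c(rows, list(data.frame(source = kept$mirna[as_gene], target = kept$target[as_gene],
                                      relation = "miRNA-gene", score = kept$total_context_score[as_gene])))
    if (any(as_tf))
      rows <- c(rows, list(data.frame(source = kept$mirna[as_tf], target = kept$target[as_tf],
                                      relation = "miRNA-TF", score = kept$total_context_score[as_tf])))
  }
  edge_store(do.call(rbind, rows), catalog)
}

#' Merge several edge stores over one catalog
#' @param ... edge stores sharing a catalog.
#' @return An [edge_store()] with the deduplicated union of edges.
#' @export
merge_edge_stores <- function(...) {
  stores <- list(...)
  stopifnot(length(stores) >= 1L)
  catalog <- stores[[1L]]$catalog
  edge_store(do.call(rbind, lapply(stores, function(s) s$edges)), catalog)
}
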