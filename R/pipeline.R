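# End-to-end orchestration of the four framework steps: load or compute the
# five edge classes, screen (TF, miRNA) pairs by the co-targeting test,
# enumerate and merge significant 3-node and 4-node FFLs, build the merged
# network plus composite / seeded subnetworks, and emit topology reports
# with a JSON summary whose rows mirror the per-class FFL accounting.

#' Parse a flat key-value pipeline config with [section] headers
#'
#' Lines are `key = value` inside `[section]` blocks; `#` comments and blank
#' lines are ignored. Values holding commas become character vectors;
#' numeric-looking values become numeric.
#'
#' @param path config file path.
#' @return nested named list (section -> key -> value).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  cfg <- list(); section <- "global"
  for (ln in lines) {
    ln <- trimws(sub("#.*$", "", ln))
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) { section <- gsub("^\\[|\\]$", "", ln); next }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (grepl(",", val, fixed = TRUE)) val <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(val))
    if (length(val) == length(num) && !anyNA(num)) val <- num
    cfg[[section]][[key]] <- val
  }
  cfg
}

#' Import merged FFLs from a targets-only TSV
#'
#' Reads a TSV with header columns `class`, `tf`, `mirna`, `targets`
#' (targets semicolon-joined; 4-node gene pairs joined by `"|"`). Arity is
#' taken from an optional `arity` column, else inferred per row from
#' pair-typed targets. Suitable for [build_network()] and the subnetwork
#' operations, bypassing enumeration.
#'
#' @param path TSV path.
#' @return a `merged_ffl_set` (without member-edge detail; network building
#'   uses the canonical template expansion).
#' @export
import_merged_ffls <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, quote = "")
  need <- c("class", "tf", "mirna", "targets")
  if (!all(need %in% names(tab)))
    stop("merged-FFL table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  bad <- which(!tab$class %in% FFL_CLASSES)
  if (length(bad))
    stop("unknown FFL class '", tab$class[bad[1L]], "' at row ", bad[1L], call. = FALSE)
  arity <- if ("arity" %in% names(tab)) tab$arity else
    ifelse(grepl("|", tab$targets, fixed = TRUE), "4-node", "3-node")
  out <- data.frame(tf = tab$tf, mirna = tab$mirna, ffl_class = tab$class,
                    arity = arity,
                    targets = tab$targets,
                    n_members = lengths(strsplit(tab$targets, ";", fixed = TRUE)),
                    stringsAsFactors = FALSE)
  class(out) <- c("merged_ffl_set", "data.frame")
  out
}

#' Write merged FFLs to the exchange TSV
#' @param merged a `merged_ffl_set`.
#' @param path output path.
#' @export
write_merged_ffls <- function(merged, path) {
  tab <- data.frame(arity = merged$arity, class = merged$ffl_class,
                    tf = merged$tf, mirna = merged$mirna, targets = merged$targets)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-class FFL accounting table
#'
#' One row per (arity, class): number of merged FFLs and the distinct node
#' and link counts their member edges contribute. TF-FFL rows have zero
#' miRNA-TF links and miRNA-FFL rows zero TF-miRNA links by construction.
#'
#' @param merged a `merged_ffl_set` with member-edge detail (template
#'   expansion is used when absent).
#' @return data frame with columns `arity`, `ffl_class`, `n_merged`,
#'   `genes`, `mirnas`, `tfs`, and one column per relation kind.
#' @export
ffl_accounting <- function(merged) {
  edges <- attr(merged, "member_edges")
  if (is.null(edges)) edges <- template_member_edges(merged)
  groups <- unique(merged[, c("arity", "ffl_class")])
  if (is.null(groups) || nrow(groups) == 0L)
    return(data.frame(arity = character(0), ffl_class = character(0)))
  do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    ar <- groups$arity[i]; cl <- groups$ffl_class[i]
    sel <- merged$arity == ar & merged$ffl_class == cl
    keys <- paste(merged$tf[sel], merged$mirna[sel], cl, ar, sep = "|")
    e <- edges[edges$ffl_key %in% keys, , drop = FALSE]
    e <- e[!duplicated(edge_key(e$source, e$target, e$relation)), , drop = FALSE]
    nodes <- node_frame_from_edges(e)
    counts <- setNames(vapply(RELATIONS, function(r) sum(e$relation == r), integer(1)),
                       RELATIONS)
    cbind(data.frame(arity = ar, ffl_class = cl, n_merged = sum(sel),
                     genes = length(unique(nodes$id[nodes$class == "gene"])),
                     mirnas = length(unique(nodes$id[nodes$class == "mirna"])),
                     tfs = length(unique(nodes$id[nodes$class == "tf"])),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts), check.names = FALSE))
  }))
}

#' Run the full FFL-network pipeline
#'
#' Stages: load catalog and edge tables -> co-targeting screen of (TF,
#' miRNA) pairs (BH FDR < alpha) -> enumerate significant 3-node and 4-node
#' FFLs -> merge by regulator pair -> build the merged network, the
#' composite-FFL subnetwork and optional seed-gene subnetworks -> topology
#' reports (degrees, hubs, feedback loops, k-clique communities). All
#' artifacts are written under `out_dir`; the summary JSON is byte-stable
#' for identical inputs and seeds.
#'
#' @param config nested list (see [read_pipeline_config()]) or a config file
#'   path. Recognised keys - `[paths]`: `genes`, `mirnas`, `tfs`, `tf_gene`,
#'   `tf_mirna`, `mirna_gene`, `mirna_tf`, `gene_gene` (TSV edge tables),
#'   `merged_ffls` (import mode, bypasses enumeration); `[thresholds]`:
#'   `alpha` (0.05), `hub_quantile` (0.2), `community_k` (3); `[subnetwork]`:
#'   `seeds` (node ids); `[output]`: `dir` (required).
#' @return invisible list with the summary, network, subnetworks and merged
#'   FFLs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  paths <- config$paths %||% list()
  thr <- config$thresholds %||% list()
  out_dir <- config$output$dir %||% stop("config needs [output] dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- thr$alpha %||% 0.05
  hub_q <- thr$hub_quantile %||% 0.20
  comm_k <- thr$community_k %||% 3L
  stage <- function(name, expr) {
    message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (!is.null(paths$merged_ffls)) {
    merged <- stage("import-ffls", import_merged_ffls(paths$merged_ffls))
    tests <- NULL
  } else {
    catalog <- stage("catalog",
      load_node_catalog(paths$genes, paths$mirnas, paths$tfs))
    rel_keys <- c(tf_gene = "TF-gene", tf_mirna = "TF-miRNA",
                  mirna_gene = "miRNA-gene", mirna_tf = "miRNA-TF",
                  gene_gene = "gene-gene")
    stores <- stage("edges", {
      lst <- list()
      for (k in names(rel_keys)) if (!is.null(paths[[k]]))
        lst[[k]] <- load_edge_table(paths[[k]], rel_keys[[k]], catalog)
      if (length(lst) == 0L) stop("no edge tables configured")
      lst
    })
    store <- do.call(merge_edge_stores, unname(stores))
    tests <- stage("cotarget-test", cotarget_tests(store))
    sig <- stage("significance-filter", significant_pairs(tests, alpha = alpha))
    message(sprintf("significant (TF, miRNA) pairs: %d/%d", nrow(sig), nrow(tests)))
    ffl3 <- stage("enumerate-3node", enumerate_3node(store, pairs = sig))
    ffl4 <- stage("enumerate-4node", enumerate_4node(store, pairs = sig))
    message(sprintf("FFLs: %d 3-node, %d 4-node", nrow(ffl3), nrow(ffl4)))
    merged <- stage("merge", bind_merged_ffls(merge_ffls(ffl3), merge_ffls(ffl4)))
  }

  network <- stage("build-network", build_network(merged))
  composite <- stage("composite-subnetwork", composite_subnetwork(merged))
  seeded <- NULL
  if (!is.null(config$subnetwork$seeds))
    seeded <- stage("seeded-subnetwork",
                    seeded_subnetwork(merged, config$subnetwork$seeds))
  degrees <- stage("degrees", degree_summary(network))
  hubs <- stage("hubs", suppressWarnings(find_hubs(network, quantile_ = hub_q)))
  loops <- stage("feedback-loops", feedback_loops(network))
  comms <- stage("communities", k_clique_communities(network, k = comm_k))

  stage("write-artifacts", {
    write_merged_ffls(merged, file.path(out_dir, "merged_ffls.tsv"))
    if (!is.null(tests))
      write.table(tests, file.path(out_dir, "cotarget_tests.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(network, file.path(out_dir, "network.sif"), "SIF")
    write_network(network, file.path(out_dir, "network.graphml"), "GraphML")
    write_network(composite, file.path(out_dir, "composite_subnetwork.sif"), "SIF")
    if (!is.null(seeded))
      write_network(seeded, file.path(out_dir, "seeded_subnetwork.sif"), "SIF")
  })

  summary_ <- list(
    ffl_accounting = ffl_accounting(merged),
    network = list(nodes = nrow(network$nodes), edges = nrow(network$edges),
                   node_classes = as.list(table(network$nodes$class)),
                   edge_relations = as.list(table(network$edges$relation))),
    composite_subnetwork = list(nodes = nrow(composite$nodes),
                                edges = nrow(composite$edges)),
    seeded_subnetwork = if (!is.null(seeded))
      list(nodes = nrow(seeded$nodes), edges = nrow(seeded$edges)),
    feedback_loops = nrow(loops),
    communities = lengths(comms),
    hubs = hubs,
    degree_by_class = degrees$by_class,
    parameters = list(alpha = alpha, hub_quantile = hub_q, community_k = comm_k))
  jsonlite::write_json(summary_, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("pipeline complete: %d nodes, %d edges",
                  nrow(network$nodes), nrow(network$edges)))
  invisible(list(summary = summary_, merged = merged, network = network,
                 composite = composite, seeded = seeded, tests = tests))
}
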