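# Feed-forward-loop discovery. A mixed FFL couples a TF and a miRNA that
# jointly regulate a target gene (3-node) or a coexpressed gene pair
# (4-node). The class of an FFL is fixed by the regulation between the two
# regulators: TF->miRNA only = TF-FFL, miRNA->TF only = miRNA-FFL, both =
# composite-FFL, neither = not an FFL. Candidate (TF, miRNA) pairs are
# screened by a cumulative hypergeometric co-targeting test with
# Benjamini-Hochberg FDR control, and surviving FFLs sharing a (TF, miRNA)
# regulation are merged into one record per pair.

FFL_CLASSES <- c("TF-FFL", "miRNA-FFL", "composite-FFL")

#' Classify the regulation between a TF and a miRNA
#'
#' @param tf,mirna identifiers present in the store's catalog.
#' @param store an [edge_store()].
#' @return `"TF-FFL"` (TF->miRNA only), `"miRNA-FFL"` (miRNA->TF only),
#'   `"composite-FFL"` (both), or `NA_character_` (neither: the pair cannot
#'   seed an FFL).
#' @export
classify_pair <- function(tf, mirna, store) {
  t2m <- has_edge(store, tf, mirna, "TF-miRNA")
  m2t <- has_edge(store, mirna, tf, "miRNA-TF")
  if (t2m && m2t) "composite-FFL"
  else if (t2m) "TF-FFL"
  else if (m2t) "miRNA-FFL"
  else NA_character_
}

# class of every (tf, mirna) pair with at least one regulator-regulator edge
classified_pairs <- function(store) {
  t2m <- edges_of(store, "TF-miRNA")
  m2t <- edges_of(store, "miRNA-TF")
  keys_t2m <- paste(t2m$source, t2m$target, sep = "\r")
  keys_m2t <- paste(m2t$target, m2t$source, sep = "\r")
  keys <- union(keys_t2m, keys_m2t)
  if (length(keys) == 0L)
    return(data.frame(tf = character(0), mirna = character(0),
                      ffl_class = character(0), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  cls <- ifelse(keys %in% keys_t2m & keys %in% keys_m2t, "composite-FFL",
                ifelse(keys %in% keys_t2m, "TF-FFL", "miRNA-FFL"))
  data.frame(tf = parts[, 1L], mirna = parts[, 2L], ffl_class = cls,
             stringsAsFactors = FALSE)
}

#' Enumerate 3-node feed-forward loops
#'
#' Returns every triple (tf, mirna, gene) such that the store contains
#' TF-gene(tf -> gene), miRNA-gene(mirna -> gene), and a regulator-regulator
#' edge giving the pair a class. Output is sorted (tf, mirna, gene).
#'
#' @param store an [edge_store()].
#' @param pairs optional data frame (`tf`, `mirna`) restricting enumeration
#'   to those regulator pairs (e.g. the significance-filtered set).
#' @return data frame of class `ffl3_set`: `tf`, `mirna`, `gene`,
#'   `ffl_class`.
#' @export
enumerate_3node <- function(store, pairs = NULL) {
  cp <- classified_pairs(store)
  if (!is.null(pairs))
    cp <- merge(cp, unique(pairs[, c("tf", "mirna")]), by = c("tf", "mirna"))
  tg <- edges_of(store, "TF-gene")
  mg <- edges_of(store, "miRNA-gene")
  out <- list()
  if (nrow(cp)) {
    tf_targets <- split(tg$target, tg$source)
    mi_targets <- split(mg$target, mg$source)
    for (i in seq_len(nrow(cp))) {
      joint <- intersect(tf_targets[[cp$tf[i]]] %||% character(0),
                         mi_targets[[cp$mirna[i]]] %||% character(0))
      if (length(joint))
        out[[length(out) + 1L]] <- data.frame(
          tf = cp$tf[i], mirna = cp$mirna[i], gene = joint,
          ffl_class = cp$ffl_class[i], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(0), mirna = character(0), gene = character(0),
               ffl_class = character(0), stringsAsFactors = FALSE)
  res <- res[order(res$tf, res$mirna, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ffl3_set", "data.frame")
  res
}

#' Enumerate 4-node feed-forward loops
#'
#' A 4-node FFL is a classified (tf, mirna) pair plus a coexpressed gene
#' pair {g1, g2} such that, under some labeling (a, b) of the pair, the
#' store contains TF-gene(tf -> a) and miRNA-gene(mirna -> b), and at least
#' one of TF-gene(tf -> b) or miRNA-gene(mirna -> a). Each unordered gene
#' pair is reported once per (tf, mirna); the logical columns `tf_g1`,
#' `tf_g2`, `mir_g1`, `mir_g2` record which regulator->gene edges are
#' present (g1 < g2 lexicographically).
#'
#' @inheritParams enumerate_3node
#' @return data frame of class `ffl4_set`: `tf`, `mirna`, `g1`, `g2`,
#'   `ffl_class`, `tf_g1`, `tf_g2`, `mir_g1`, `mir_g2`.
#' @export
enumerate_4node <- function(store, pairs = NULL) {
  cp <- classified_pairs(store)
  if (!is.null(pairs))
    cp <- merge(cp, unique(pairs[, c("tf", "mirna")]), by = c("tf", "mirna"))
  gg <- edges_of(store, "gene-gene")
  tg <- edges_of(store, "TF-gene")
  mg <- edges_of(store, "miRNA-gene")
  empty <- data.frame(tf = character(0), mirna = character(0), g1 = character(0),
                      g2 = character(0), ffl_class = character(0),
                      tf_g1 = logical(0), tf_g2 = logical(0),
                      mir_g1 = logical(0), mir_g2 = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(cp) == 0L || nrow(gg) == 0L) {
    class(empty) <- c("ffl4_set", "data.frame")
    return(empty)
  }
  tf_targets <- split(tg$target, tg$source)
  mi_targets <- split(mg$target, mg$source)
  out <- list()
  for (i in seq_len(nrow(cp))) {
    tt <- tf_targets[[cp$tf[i]]] %||% character(0)
    mt <- mi_targets[[cp$mirna[i]]] %||% character(0)
    if (length(tt) == 0L || length(mt) == 0L) next
    t1 <- gg$source %in% tt; t2 <- gg$target %in% tt
    m1 <- gg$source %in% mt; m2 <- gg$target %in% mt
    # labeling (a=g1, b=g2): t1 & m2 & (t2 | m1); labeling (a=g2, b=g1): t2 & m1 & (t1 | m2)
    ok <- (t1 & m2 & (t2 | m1)) | (t2 & m1 & (t1 | m2))
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        tf = cp$tf[i], mirna = cp$mirna[i],
        g1 = gg$source[ok], g2 = gg$target[ok], ffl_class = cp$ffl_class[i],
        tf_g1 = t1[ok], tf_g2 = t2[ok], mir_g1 = m1[ok], mir_g2 = m2[ok],
        stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$tf, res$mirna, res$g1, res$g2), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ffl4_set", "data.frame")
  res
}

#' Cumulative hypergeometric co-targeting p-value
#'
#' Upper-tail probability P(X >= x) for X ~ Hypergeometric(total, m, n):
#' the chance that a random size-n draw from a universe of `total` genes,
#' `m` of which are targets of the miRNA, contains at least `x` of them.
#' The default path sums the upper-tail terms explicitly from log binomial
#' coefficients; `exact = FALSE` uses `stats::phyper`.
#'
#' @param m genes targeted by the miRNA.
#' @param n genes regulated by the TF.
#' @param x jointly targeted genes.
#' @param total size of the common target universe.
#' @param exact use the explicit term summation (default TRUE).
#' @return p-value in (0, 1].
#' @export
cotarget_pvalue <- function(m, n, x, total, exact = TRUE) {
  if (any(c(m, n, x, total) < 0) || x > min(m, n) || m > total || n > total)
    stop("invalid hypergeometric bounds: need 0 <= x <= min(m,n) <= total",
         call. = FALSE)
  if (x == 0L) return(1)
  if (exact) {
    k <- seq.int(x, min(m, n))
    sum(exp(lchoose(m, k) + lchoose(total - m, n - k) - lchoose(total, n)))
  } else {
    phyper(x - 1, m, total - m, n, lower.tail = FALSE)
  }
}

#' Co-targeting tests for every classified (TF, miRNA) pair
#'
#' For each (tf, mirna) pair carrying a regulator-regulator edge, counts the
#' miRNA's gene targets (m), the TF's gene targets (n), and the overlap (x)
#' over a common target universe, then applies [cotarget_pvalue()]. The
#' universe and per-regulator target maps default to the analysis store but
#' can be supplied as genome-wide background maps.
#'
#' @param store an [edge_store()].
#' @param background optional list with elements `mirna_targets` (named list
#'   miRNA -> gene vector), `tf_targets` (named list TF -> gene vector); when
#'   given, m/n/x/total are computed on the background maps.
#' @param total optional explicit universe size override.
#' @return data frame: `mirna`, `tf`, `m`, `n`, `x`, `total`, `p`.
#' @export
cotarget_tests <- function(store, background = NULL, total = NULL) {
  cp <- classified_pairs(store)
  if (is.null(background)) {
    tg <- edges_of(store, "TF-gene")
    mg <- edges_of(store, "miRNA-gene")
    tf_targets <- split(tg$target, tg$source)
    mi_targets <- split(mg$target, mg$source)
  } else {
    tf_targets <- background$tf_targets
    mi_targets <- background$mirna_targets
  }
  universe <- intersect(unique(unlist(mi_targets)), unique(unlist(tf_targets)))
  tot <- if (is.null(total)) length(universe) else as.integer(total)
  message(sprintf("co-targeting universe: %d genes (%s)", tot,
                  if (is.null(background)) "analysis store" else "background maps"))
  if (nrow(cp) == 0L || tot == 0L)
    return(data.frame(mirna = character(0), tf = character(0), m = integer(0),
                      n = integer(0), x = integer(0), total = integer(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, lapply(seq_len(nrow(cp)), function(i) {
    mt <- intersect(mi_targets[[cp$mirna[i]]] %||% character(0), universe)
    tt <- intersect(tf_targets[[cp$tf[i]]] %||% character(0), universe)
    data.frame(mirna = cp$mirna[i], tf = cp$tf[i],
               m = length(mt), n = length(tt), x = length(intersect(mt, tt)),
               total = tot, stringsAsFactors = FALSE)
  }))
  res$p <- vapply(seq_len(nrow(res)), function(i)
    cotarget_pvalue(res$m[i], res$n[i], res$x[i], res$total[i]), numeric(1))
  res[order(res$mirna, res$tf), , drop = FALSE]
}

#' Keep significantly co-targeting (TF, miRNA) pairs
#'
#' Attaches Benjamini-Hochberg adjusted q-values (via [bh_fdr()]) and keeps
#' pairs with q strictly below `alpha`.
#'
#' @param tests data frame as from [cotarget_tests()] (needs column `p`).
#' @param alpha FDR level (default 0.05).
#' @return the filtered data frame with an added `q` column.
#' @export
significant_pairs <- function(tests, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (nrow(tests) == 0L) { tests$q <- numeric(0); return(tests) }
  tests$q <- bh_fdr(tests$p)
  out <- tests[tests$q < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge FFLs sharing a (TF, miRNA) regulation
#'
#' Groups FFLs of one arity by their regulator pair. Targets of a merged
#' 3-node record are the member genes; targets of a merged 4-node record are
#' the member gene pairs joined by `"|"`. The sum of target counts over all
#' merged records equals the number of input FFLs.
#'
#' @param ffls an `ffl3_set` or `ffl4_set`.
#' @return data frame of class `merged_ffl_set`: `tf`, `mirna`, `ffl_class`,
#'   `arity` (`"3-node"`/`"4-node"`), `targets` (semicolon-joined),
#'   `n_members`, plus a `member_edges` attribute used to rebuild networks
#'   exactly.
#' @export
merge_ffls <- function(ffls) {
  if (inherits(ffls, "ffl3_set")) arity <- "3-node"
  else if (inherits(ffls, "ffl4_set")) arity <- "4-node"
  else stop("input must be an ffl3_set or ffl4_set (single arity)", call. = FALSE)
  if (nrow(ffls) == 0L) {
    out <- data.frame(tf = character(0), mirna = character(0),
                      ffl_class = character(0), arity = character(0),
                      targets = character(0), n_members = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("merged_ffl_set", "data.frame")
    return(out)
  }
  key <- paste(ffls$tf, ffls$mirna, sep = "\r")
  grp <- split(seq_len(nrow(ffls)), key)
  out <- do.call(rbind, lapply(grp, function(idx) {
    f <- ffls[idx, , drop = FALSE]
    tgt <- if (arity == "3-node") sort(unique(f$gene))
           else sort(unique(paste(f$g1, f$g2, sep = "|")))
    data.frame(tf = f$tf[1L], mirna = f$mirna[1L], ffl_class = f$ffl_class[1L],
               arity = arity, targets = paste(tgt, collapse = ";"),
               n_members = length(tgt), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$tf, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "member_edges") <- ffl_member_edges(ffls, arity)
  class(out) <- c("merged_ffl_set", "data.frame")
  out
}

# constituent regulatory edges of each FFL, tagged by merged key
ffl_member_edges <- function(ffls, arity) {
  if (nrow(ffls) == 0L) return(NULL)
  rows <- lapply(seq_len(nrow(ffls)), function(i) {
    f <- ffls[i, ]
    key <- paste(f$tf, f$mirna, f$ffl_class, arity, sep = "|")
    reg <- switch(f$ffl_class,
      "TF-FFL" = data.frame(source = f$tf, target = f$mirna, relation = "TF-miRNA"),
      "miRNA-FFL" = data.frame(source = f$mirna, target = f$tf, relation = "miRNA-TF"),
      "composite-FFL" = data.frame(source = c(f$tf, f$mirna), target = c(f$mirna, f$tf),
                                   relation = c("TF-miRNA", "miRNA-TF")))
    tgt <- if (arity == "3-node") {
      data.frame(source = c(f$tf, f$mirna), target = c(f$gene, f$gene),
                 relation = c("TF-gene", "miRNA-gene"))
    } else {
      rbind(
        data.frame(source = f$g1, target = f$g2, relation = "gene-gene"),
        if (f$tf_g1) data.frame(source = f$tf, target = f$g1, relation = "TF-gene"),
        if (f$tf_g2) data.frame(source = f$tf, target = f$g2, relation = "TF-gene"),
        if (f$mir_g1) data.frame(source = f$mirna, target = f$g1, relation = "miRNA-gene"),
        if (f$mir_g2) data.frame(source = f$mirna, target = f$g2, relation = "miRNA-gene"))
    }
    e <- rbind(reg, tgt)
    e$ffl_key <- key
    e
  })
  do.call(rbind, rows)
}

#' Flatten merged FFLs back to one row per member target
#' @param merged a `merged_ffl_set`.
#' @return data frame `tf`, `mirna`, `ffl_class`, `arity`, `target`.
#' @export
flatten_merged_ffls <- function(merged) {
  if (nrow(merged) == 0L)
    return(data.frame(tf = character(0), mirna = character(0),
                      ffl_class = character(0), arity = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    data.frame(tf = merged$tf[i], mirna = merged$mirna[i],
               ffl_class = merged$ffl_class[i], arity = merged$arity[i],
               target = strsplit(merged$targets[i], ";", fixed = TRUE)[[1L]],
               stringsAsFactors = FALSE)
  }))
}

#' Combine merged FFL sets of both arities
#' @param ... `merged_ffl_set` objects.
#' @return a `merged_ffl_set` with member-edge attributes concatenated.
#' @export
bind_merged_ffls <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  edges <- do.call(rbind, lapply(sets, attr, "member_edges"))
  out <- do.call(rbind, lapply(sets, function(s) { attr(s, "member_edges") <- NULL; s }))
  rownames(out) <- NULL
  attr(out, "member_edges") <- edges
  class(out) <- c("merged_ffl_set", "data.frame")
  out
}
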