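# Independent brute-force oracles used to validate the package's
# implementations, plus small fixture builders. Oracles deliberately use
# naive enumeration / set algebra, not the code paths they check.

tiny_catalog <- function(n_tf = 4L, n_mirna = 4L, n_gene = 6L) {
  node_catalog(paste0("g", seq_len(n_gene)),
               paste0("miR", seq_len(n_mirna)),
               paste0("TF", seq_len(n_tf)))
}

# random typed edge store over a small catalog
random_store <- function(seed, n_tf = 3L, n_mirna = 3L, n_gene = 6L, density = 0.2) {
  set.seed(seed)
  catalog <- tiny_catalog(n_tf, n_mirna, n_gene)
  rows <- list()
  maybe <- function(src, tgt, rel) {
    for (s in src) for (t in tgt) if (runif(1) < density)
      rows[[length(rows) + 1L]] <<- data.frame(source = s, target = t, relation = rel)
  }
  maybe(catalog$tfs, catalog$genes, "TF-gene")
  maybe(catalog$tfs, catalog$mirnas, "TF-miRNA")
  maybe(catalog$mirnas, catalog$genes, "miRNA-gene")
  maybe(catalog$mirnas, catalog$tfs, "miRNA-TF")
  gg <- t(combn(catalog$genes, 2L))
  for (i in seq_len(nrow(gg))) if (runif(1) < density)
    rows[[length(rows) + 1L]] <- data.frame(source = gg[i, 1L], target = gg[i, 2L],
                                            relation = "gene-gene")
  edges <- if (length(rows)) do.call(rbind, rows) else NULL
  edge_store(edges, catalog)
}

store_has <- function(store, s, t, rel) {
  e <- store$edges
  any(e$source == s & e$target == t & e$relation == rel)
}

oracle_classify <- function(tf, mirna, store) {
  t2m <- store_has(store, tf, mirna, "TF-miRNA")
  m2t <- store_has(store, mirna, tf, "miRNA-TF")
  if (t2m && m2t) "composite-FFL" else if (t2m) "TF-FFL" else if (m2t) "miRNA-FFL"
  else NA_character_
}

oracle_3node <- function(store) {
  cat_ <- store$catalog
  out <- list()
  for (tf in cat_$tfs) for (mi in cat_$mirnas) {
    cls <- oracle_classify(tf, mi, store)
    if (is.na(cls)) next
    for (g in cat_$genes) {
      if (store_has(store, tf, g, "TF-gene") && store_has(store, mi, g, "miRNA-gene"))
        out[[length(out) + 1L]] <- data.frame(tf = tf, mirna = mi, gene = g,
                                              ffl_class = cls)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(0), mirna = character(0), gene = character(0),
               ffl_class = character(0))
  res[order(res$tf, res$mirna, res$gene), , drop = FALSE]
}

oracle_4node <- function(store) {
  cat_ <- store$catalog
  gg <- store$edges[store$edges$relation == "gene-gene", , drop = FALSE]
  out <- list()
  for (tf in cat_$tfs) for (mi in cat_$mirnas) {
    cls <- oracle_classify(tf, mi, store)
    if (is.na(cls)) next
    for (i in seq_len(nrow(gg))) {
      g1 <- gg$source[i]; g2 <- gg$target[i]
      tg <- function(g) store_has(store, tf, g, "TF-gene")
      mg <- function(g) store_has(store, mi, g, "miRNA-gene")
      lab1 <- tg(g1) && mg(g2) && (tg(g2) || mg(g1))
      lab2 <- tg(g2) && mg(g1) && (tg(g1) || mg(g2))
      if (lab1 || lab2)
        out[[length(out) + 1L]] <- data.frame(tf = tf, mirna = mi, g1 = g1, g2 = g2,
                                              ffl_class = cls)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(0), mirna = character(0), g1 = character(0),
               g2 = character(0), ffl_class = character(0))
  res[order(res$tf, res$mirna, res$g1, res$g2), , drop = FALSE]
}

# upper-tail hypergeometric by enumeration over the full support with
# stats::dhyper as the independent density
oracle_cotarget <- function(m, n, x, total) {
  support <- max(0L, n - (total - m)):min(m, n)
  sum(dhyper(support[support >= x], m, total - m, n))
}

# Fisher p by enumeration over all tables with the observed margins,
# probabilities from choose() directly
oracle_fisher <- function(a, b, c_, d, alternative) {
  m <- a + b; n_ <- c_ + d; k <- a + c_
  lo <- max(0L, k - n_); hi <- min(m, k)
  probs <- vapply(lo:hi, function(aa)
    choose(m, aa) * choose(n_, k - aa) / choose(m + n_, k), numeric(1))
  names(probs) <- lo:hi
  if (alternative == "greater") sum(probs[as.integer(names(probs)) >= a])
  else sum(probs[probs <= probs[as.character(a)] * (1 + 1e-7)])
}

# all-triangles DPI scan over node triples
oracle_dpi <- function(edges, tolerance) {
  key <- function(p, q) paste(pmin(p, q), pmax(p, q), sep = "\r")
  w <- setNames(edges$score, key(edges$source, edges$target))
  nodes <- sort(unique(c(edges$source, edges$target)))
  drop <- character(0)
  if (length(nodes) >= 3L) {
    for (trip in asplit(combn(nodes, 3L), 2L)) {
      ks <- c(key(trip[1L], trip[2L]), key(trip[2L], trip[3L]), key(trip[1L], trip[3L]))
      if (any(is.na(w[ks]))) next
      for (i in 1:3) {
        others <- w[ks[-i]]
        if (w[ks[i]] < min(others) * (1 - tolerance)) drop <- c(drop, ks[i])
      }
    }
  }
  edges[!(key(edges$source, edges$target) %in% drop), , drop = FALSE]
}

# clique percolation by exhaustive k-subset enumeration + BFS on the
# shared-(k-1) relation
oracle_kclique <- function(edges, nodes, k) {
  adj <- function(a, b) any((edges$source == a & edges$target == b) |
                            (edges$source == b & edges$target == a))
  if (length(nodes) < k) return(list())
  subsets <- asplit(combn(sort(nodes), k), 2L)
  is_clique <- vapply(subsets, function(s) {
    all(apply(combn(s, 2L), 2L, function(p) adj(p[1L], p[2L])))
  }, logical(1))
  cl <- subsets[is_clique]
  if (length(cl) == 0L) return(list())
  n <- length(cl)
  seen <- rep(FALSE, n)
  comms <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    queue <- i; comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      if (seen[cur]) next
      seen[cur] <- TRUE; comp <- c(comp, cur)
      for (j in seq_len(n)) if (!seen[j] &&
          length(intersect(cl[[cur]], cl[[j]])) == k - 1L) queue <- c(queue, j)
    }
    comms[[length(comms) + 1L]] <- sort(unique(unlist(cl[comp])))
  }
  comms[order(-lengths(comms),
              vapply(comms, paste, character(1), collapse = "|"))]
}

# connected-component count by BFS over an undirected edge list
oracle_components <- function(edges, nodes) {
  nbr <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$source[i]; b <- edges$target[i]
    nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
  }
  seen <- character(0); n_comp <- 0L
  for (v in nodes) {
    if (v %in% seen) next
    n_comp <- n_comp + 1L
    queue <- v
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      if (cur %in% seen) next
      seen <- c(seen, cur)
      queue <- c(queue, setdiff(nbr[[cur]], seen))
    }
  }
  n_comp
}

# one-sided KS by scanning the supremum over the pooled sample points
oracle_ks_greater <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  D <- max(vapply(pts, function(t) mean(b <= t) - mean(a <= t), numeric(1)), 0)
  p <- min(1, exp(-2 * D^2 * length(a) * length(b) / (length(a) + length(b))))
  c(D = D, p = p)
}

# per-window scanner oracle: score every offset on both strands via
# similarity_scores
oracle_scan <- function(pwm_, prom, core_cutoff, matrix_cutoff) {
  L <- pwm_$length
  seq_ <- prom$sequence
  n <- nchar(seq_)
  revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  out <- list()
  for (s in 0:(n - L)) {
    win <- substr(seq_, s + 1L, s + L)
    if (grepl("N", win, fixed = TRUE)) next
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else revcomp(win)
      sc <- similarity_scores(pwm_, w)
      if (sc["core_score"] >= core_cutoff && sc["matrix_score"] >= matrix_cutoff)
        out[[length(out) + 1L]] <- data.frame(
          tf = pwm_$name, node = prom$node, species = prom$species,
          position = s, strand = strand,
          core_score = unname(sc["core_score"]),
          matrix_score = unname(sc["matrix_score"]))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(0), node = character(0), species = character(0),
               position = integer(0), strand = character(0),
               core_score = numeric(0), matrix_score = numeric(0))
  res <- res[order(res$tf, res$node, res$species, res$position, res$strand), ]
  rownames(res) <- NULL
  res
}

toy_pwm <- function(name = "TFX", seed = NULL, L = 6L) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(rpois(4L * L, 3) + 1, nrow = 4L)
  pwm(name, counts)
}
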