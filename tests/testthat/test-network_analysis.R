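minimal_tf_ffl <- function() {
  s <- edge_store(data.frame(
    source = c("TF1", "miR1", "TF1"),
    target = c("g1", "g1", "miR1"),
    relation = c("TF-gene", "miRNA-gene", "TF-miRNA")), tiny_catalog())
  merge_ffls(enumerate_3node(s))
}

random_merged <- function(seed, density = 0.3) {
  store <- random_store(seed, n_tf = 4, n_mirna = 4, n_gene = 8, density = density)
  bind_merged_ffls(merge_ffls(enumerate_3node(store)),
                   merge_ffls(enumerate_4node(store)))
}

test_that("a minimal TF-FFL expands to 3 nodes and 3 edges, idempotently", {
  merged <- minimal_tf_ffl()
  net <- build_network(merged)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(net$edges$relation, c("TF-gene", "miRNA-gene", "TF-miRNA"))
  twice <- build_network(bind_merged_ffls(merged, merged))
  expect_identical(twice$edges, net$edges)
  expect_identical(twice$nodes, net$nodes)
})

test_that("edge provenance is non-empty and regenerates the edge set", {
  for (seed in c(3, 11, 42)) {
    merged <- random_merged(seed)
    net <- build_network(merged)
    if (nrow(net$edges) == 0L) next
    keys <- edge_key(net$edges$source, net$edges$target, net$edges$relation)
    expect_true(all(keys %in% names(net$provenance)))
    expect_true(all(lengths(net$provenance[keys]) >= 1L))
    # re-expanding the merged FFLs named in provenance regenerates every edge
    all_keys <- paste(merged$tf, merged$mirna, merged$ffl_class, merged$arity, sep = "|")
    expect_true(all(unlist(net$provenance) %in% all_keys))
  }
})

test_that("degree summary: K3 degrees, handshake lemma, per-class means", {
  merged <- minimal_tf_ffl()
  net <- build_network(merged)
  ds <- degree_summary(net)
  expect_true(all(ds$degrees == 2))  # triangle
  for (seed in c(5, 23)) {
    m <- random_merged(seed)
    n <- build_network(m)
    if (nrow(n$edges) == 0L) next
    ds <- degree_summary(n)
    g <- as_undirected_graph(n)
    expect_equal(sum(ds$degrees), 2L * igraph::ecount(g))
    expect_equal(sum(ds$by_class$n), nrow(n$nodes))
    # distribution fractions sum to 1 within each class
    for (cl in unique(ds$distribution$class))
      expect_equal(sum(ds$distribution$fraction[ds$distribution$class == cl]), 1)
  }
})

test_that("hub calling keeps the clear top node and guards degenerate classes", {
  # star: TF1 regulates 10 genes through one miRNA -> TF1 and miR1 dominate
  edges <- rbind(
    data.frame(source = "TF1", target = paste0("g", 1:10), relation = "TF-gene"),
    data.frame(source = "miR1", target = paste0("g", 1:10), relation = "miRNA-gene"),
    data.frame(source = "TF1", target = "miR1", relation = "TF-miRNA"))
  s <- edge_store(edges, node_catalog(paste0("g", 1:10), "miR1", "TF1"))
  net <- build_network(merge_ffls(enumerate_3node(s)))
  hubs <- suppressWarnings(find_hubs(net, quantile_ = 0.2))
  # genes all have equal degree 2 -> median guard suppresses gene hubs
  expect_false("gene" %in% hubs$class && nzchar(hubs$hubs[hubs$class == "gene"]))
  expect_error(find_hubs(net, quantile_ = 0), "quantile")
  empty <- regulatory_network(data.frame(id = character(0), class = character(0)), NULL)
  expect_equal(nrow(find_hubs(empty)), 0L)
})

test_that("hub cutoffs are scale-consistent under disjoint duplication", {
  merged <- random_merged(31)
  net <- build_network(merged)
  expect_gt(nrow(net$edges), 0L)
  # duplicate the network with renamed nodes
  ren <- function(x) paste0(x, "_copy")
  nodes2 <- net$nodes; nodes2$id <- ren(nodes2$id)
  edges2 <- net$edges; edges2$source <- ren(edges2$source); edges2$target <- ren(edges2$target)
  dup_nodes <- rbind(net$nodes[, c("id", "class")], nodes2[, c("id", "class")])
  dup <- regulatory_network(dup_nodes, rbind(net$edges, edges2))
  h1 <- suppressWarnings(find_hubs(net))
  h2 <- suppressWarnings(find_hubs(dup))
  shared <- intersect(h1$class, h2$class)
  expect_equal(h1$cutoff[match(shared, h1$class)],
               h2$cutoff[match(shared, h2$class)])
})

test_that("composite subnetwork is the composite-only restriction of the full build", {
  for (seed in c(7, 19, 55)) {
    merged <- random_merged(seed)
    full <- build_network(merged)
    comp <- composite_subnetwork(merged)
    key <- function(n) edge_key(n$edges$source, n$edges$target, n$edges$relation)
    expect_true(all(key(comp) %in% key(full)))
    if (nrow(comp$edges)) {
      prov_classes <- unique(vapply(strsplit(unlist(comp$provenance), "|", fixed = TRUE),
                                    function(p) p[3L], character(1)))
      expect_equal(prov_classes, "composite-FFL")
    }
  }
  no_comp <- minimal_tf_ffl()
  expect_equal(nrow(composite_subnetwork(no_comp)$edges), 0L)
})

test_that("seeded subnetworks: absent seed empty, full seed cover equals the network", {
  merged <- random_merged(13)
  full <- build_network(merged)
  expect_equal(nrow(seeded_subnetwork(merged, "not-a-node")$edges), 0L)
  all_nodes <- unique(c(merged$tf, merged$mirna,
                        unlist(strsplit(unlist(strsplit(merged$targets, ";")), "\\|"))))
  cover <- seeded_subnetwork(merged, all_nodes)
  expect_identical(cover$edges, full$edges)
  expect_error(seeded_subnetwork(merged, character(0)), "non-empty")
})

test_that("seeded subnetwork keeps exactly the FFLs touching the seeds", {
  merged <- random_merged(21)
  expect_gt(nrow(merged), 1L)
  seed_gene <- strsplit(merged$targets[1], "[;|]")[[1]][1]
  sub <- seeded_subnetwork(merged, seed_gene)
  keep <- vapply(seq_len(nrow(merged)), function(i) {
    tgt <- unlist(strsplit(strsplit(merged$targets[i], ";")[[1]], "\\|"))
    seed_gene %in% c(merged$tf[i], merged$mirna[i], tgt)
  }, logical(1))
  want <- build_network(mirtfnet:::subset_merged(merged, keep))
  expect_identical(sub$edges, want$edges)
})

test_that("feedback loops are exactly the reciprocal TF/miRNA pairs", {
  s <- edge_store(data.frame(
    source = c("TF1", "miR1", "TF2", "miR1", "TF1"),
    target = c("miR1", "TF1", "miR2", "g1", "g1"),
    relation = c("TF-miRNA", "miRNA-TF", "TF-miRNA", "miRNA-gene", "TF-gene")),
    tiny_catalog())
  loops <- feedback_loops(s)
  expect_equal(nrow(loops), 1L)
  expect_equal(loops$tf, "TF1"); expect_equal(loops$mirna, "miR1")
  one_way <- edge_store(data.frame(source = "TF2", target = "miR2",
                                   relation = "TF-miRNA"), tiny_catalog())
  expect_equal(nrow(feedback_loops(one_way)), 0L)
})

test_that("k-clique communities: shared-edge triangles percolate, disjoint stay apart", {
  tri2 <- data.frame(id = c("a", "b", "c", "d"), class = "gene")
  net <- regulatory_network(tri2, data.frame(
    source = c("a", "a", "b", "b", "c"),
    target = c("b", "c", "c", "d", "d"),
    relation = "gene-gene"))
  comm <- k_clique_communities(net, k = 3)
  expect_length(comm, 1L)
  expect_equal(comm[[1]], c("a", "b", "c", "d"))

  nodes <- data.frame(id = c("a", "b", "c", "x", "y", "z"), class = "gene")
  net2 <- regulatory_network(nodes, data.frame(
    source = c("a", "a", "b", "x", "x", "y"),
    target = c("b", "c", "c", "y", "z", "z"),
    relation = "gene-gene"))
  comm2 <- k_clique_communities(net2, k = 3)
  expect_length(comm2, 2L)
})

test_that("k-clique communities match the exhaustive oracle; k = 2 gives components", {
  for (seed in c(2, 9, 33)) {
    set.seed(seed)
    n <- 12
    ids <- paste0("n", seq_len(n))
    cmb <- t(combn(ids, 2))
    take <- runif(nrow(cmb)) < 0.25
    edges <- data.frame(source = cmb[take, 1], target = cmb[take, 2],
                        relation = "gene-gene")
    net <- regulatory_network(data.frame(id = ids, class = "gene"), edges)
    for (k in c(3, 4)) {
      got <- k_clique_communities(net, k)
      want <- oracle_kclique(edges, ids, k)
      expect_equal(got, want, label = paste("seed", seed, "k", k))
    }
    comm2 <- k_clique_communities(net, k = 2)
    comp <- igraph::components(as_undirected_graph(net))
    members <- lapply(split(names(comp$membership), comp$membership), sort)
    members <- unname(members[lengths(members) >= 2L])  # isolated nodes hold no edge
    expect_setequal(comm2, members)
  }
})

test_that("node ablation removes incident edges and reports component change", {
  nodes <- data.frame(id = c("a", "b", "c"), class = "gene")
  path <- regulatory_network(nodes, data.frame(
    source = c("a", "b"), target = c("b", "c"), relation = "gene-gene"))
  cut <- ablate_nodes(path, "b")
  expect_equal(sort(cut$nodes$id), c("a", "c"))
  expect_equal(nrow(cut$edges), 0L)
  expect_equal(attr(cut, "components"), c(before = 1L, after = 2L))
  same <- ablate_nodes(path, character(0))
  expect_identical(same$edges, path$edges)
  expect_equal(attr(same, "components"), c(before = 1L, after = 1L))
})

test_that("ablation component counts match a BFS oracle on random graphs", {
  for (seed in c(4, 16, 28)) {
    merged <- random_merged(seed)
    net <- build_network(merged)
    if (nrow(net$nodes) < 4L) next
    set.seed(seed)
    victims <- sample(net$nodes$id, 2L)
    out <- ablate_nodes(net, victims)
    comp <- attr(out, "components")
    expect_equal(unname(comp["before"]),
                 oracle_components(net$edges, net$nodes$id))
    expect_equal(unname(comp["after"]),
                 oracle_components(out$edges, out$nodes$id))
  }
})
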