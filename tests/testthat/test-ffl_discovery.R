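make_store <- function(edges, n_gene = 9L) {
  edge_store(edges, tiny_catalog(n_gene = n_gene))
}

test_that("pair classification follows the regulator-regulator truth table", {
  base <- data.frame(source = c("TF1", "miR1"), target = c("g1", "g1"),
                     relation = c("TF-gene", "miRNA-gene"))
  s_none <- make_store(base)
  expect_true(is.na(classify_pair("TF1", "miR1", s_none)))
  s_tf <- make_store(rbind(base, data.frame(source = "TF1", target = "miR1",
                                            relation = "TF-miRNA")))
  expect_equal(classify_pair("TF1", "miR1", s_tf), "TF-FFL")
  s_mi <- make_store(rbind(base, data.frame(source = "miR1", target = "TF1",
                                            relation = "miRNA-TF")))
  expect_equal(classify_pair("TF1", "miR1", s_mi), "miRNA-FFL")
  s_both <- make_store(rbind(base,
                             data.frame(source = c("TF1", "miR1"),
                                        target = c("miR1", "TF1"),
                                        relation = c("TF-miRNA", "miRNA-TF"))))
  expect_equal(classify_pair("TF1", "miR1", s_both), "composite-FFL")
})

test_that("minimal 3-node and 4-node instances are enumerated", {
  s <- make_store(data.frame(
    source = c("TF1", "miR1", "TF1"),
    target = c("g1", "g1", "miR1"),
    relation = c("TF-gene", "miRNA-gene", "TF-miRNA")))
  f3 <- enumerate_3node(s)
  expect_equal(nrow(f3), 1L)
  expect_equal(f3$ffl_class, "TF-FFL")
  expect_equal(f3[, c("tf", "mirna", "gene")],
               data.frame(tf = "TF1", mirna = "miR1", gene = "g1"),
               ignore_attr = TRUE)

  s4 <- make_store(data.frame(
    source = c("g1", "TF1", "TF1", "miR1", "TF1"),
    target = c("g2", "g1", "g2", "g2", "miR1"),
    relation = c("gene-gene", "TF-gene", "TF-gene", "miRNA-gene", "TF-miRNA")))
  f4 <- enumerate_4node(s4)
  expect_equal(nrow(f4), 1L)
  expect_equal(f4$ffl_class, "TF-FFL")
  expect_equal(f4$g1, "g1"); expect_equal(f4$g2, "g2")

  # no TF-gene edges -> no 3-node FFLs; no gene-gene edges -> no 4-node FFLs
  s_empty <- make_store(data.frame(source = "miR1", target = "g1",
                                   relation = "miRNA-gene"))
  expect_equal(nrow(enumerate_3node(s_empty)), 0L)
  expect_equal(nrow(enumerate_4node(s_empty)), 0L)
})

test_that("a 4-node unit lacking both optional edges is not an FFL", {
  s <- make_store(data.frame(
    source = c("g1", "TF1", "miR1", "TF1"),
    target = c("g2", "g1", "g2", "miR1"),
    relation = c("gene-gene", "TF-gene", "miRNA-gene", "TF-miRNA")))
  expect_equal(nrow(enumerate_4node(s)), 0L)
})

test_that("enumeration matches the brute-force oracle on random stores", {
  for (seed in 1:30) {
    store <- random_store(seed, n_tf = 3, n_mirna = 3, n_gene = 6, density = 0.2)
    f3 <- enumerate_3node(store)
    o3 <- oracle_3node(store)
    expect_equal(nrow(f3), nrow(o3), label = paste("seed", seed))
    if (nrow(f3)) {
      expect_equal(paste(f3$tf, f3$mirna, f3$gene, f3$ffl_class),
                   paste(o3$tf, o3$mirna, o3$gene, o3$ffl_class))
    }
    f4 <- enumerate_4node(store)
    o4 <- oracle_4node(store)
    expect_equal(nrow(f4), nrow(o4), label = paste("seed", seed))
    if (nrow(f4)) {
      expect_equal(paste(f4$tf, f4$mirna, f4$g1, f4$g2, f4$ffl_class),
                   paste(o4$tf, o4$mirna, o4$g1, o4$g2, o4$ffl_class))
    }
  }
})

test_that("every enumerated FFL has exactly one class and the link pattern matches it", {
  store <- random_store(99, n_tf = 4, n_mirna = 4, n_gene = 8, density = 0.3)
  f3 <- enumerate_3node(store)
  expect_true(all(f3$ffl_class %in% c("TF-FFL", "miRNA-FFL", "composite-FFL")))
  merged <- merge_ffls(f3)
  acct <- ffl_accounting(merged)
  # TF-FFL rows contribute no miRNA-TF links; miRNA-FFL rows no TF-miRNA links
  if ("TF-FFL" %in% acct$ffl_class)
    expect_equal(acct[acct$ffl_class == "TF-FFL", "miRNA-TF"], 0L)
  if ("miRNA-FFL" %in% acct$ffl_class)
    expect_equal(acct[acct$ffl_class == "miRNA-FFL", "TF-miRNA"], 0L)
  if ("composite-FFL" %in% acct$ffl_class) {
    expect_gt(acct[acct$ffl_class == "composite-FFL", "miRNA-TF"], 0L)
    expect_gt(acct[acct$ffl_class == "composite-FFL", "TF-miRNA"], 0L)
  }
})

test_that("co-targeting p-value: degenerate and enumerated cases", {
  expect_equal(cotarget_pvalue(4, 5, 0, 10), 1)
  expect_equal(cotarget_pvalue(10, 5, 5, 10), 1)  # m = total forces overlap = n
  expect_equal(cotarget_pvalue(4, 5, 3, 10), 66 / 252, tolerance = 1e-12)
  expect_error(cotarget_pvalue(4, 5, 6, 10), "bounds")
  expect_error(cotarget_pvalue(11, 5, 2, 10), "bounds")
})

test_that("exact summation agrees with phyper and the enumeration oracle", {
  set.seed(5)
  for (i in 1:40) {
    total <- sample(5:60, 1)
    m <- sample(1:total, 1); n <- sample(1:total, 1)
    lo <- max(0L, m + n - total)
    x <- sample(lo:min(m, n), 1)
    p_exact <- cotarget_pvalue(m, n, x, total, exact = TRUE)
    p_lib <- cotarget_pvalue(m, n, x, total, exact = FALSE)
    p_oracle <- oracle_cotarget(m, n, x, total)
    expect_equal(p_exact, p_oracle, tolerance = 1e-12)
    expect_equal(p_exact, p_lib, tolerance = 1e-12)
  }
})

test_that("significance filter applies BH adjustment with strict alpha", {
  one <- data.frame(mirna = "miR1", tf = "TF1", m = 3, n = 3, x = 3, total = 10,
                    p = 0.01)
  kept <- significant_pairs(one, alpha = 0.05)
  expect_equal(kept$q, 0.01)

  three <- data.frame(mirna = paste0("miR", 1:3), tf = "TF1", m = 3, n = 3,
                      x = 2, total = 10, p = rep(0.04, 3))
  kept3 <- significant_pairs(three, alpha = 0.05)
  expect_equal(nrow(kept3), 3L)
  expect_equal(kept3$q, rep(0.04, 3))

  border <- data.frame(mirna = "miR1", tf = "TF1", m = 3, n = 3, x = 2,
                       total = 10, p = 0.05)
  expect_equal(nrow(significant_pairs(border, alpha = 0.05)), 0L)
})

test_that("cotarget_tests computes m, n, x over the shared target universe", {
  s <- make_store(data.frame(
    source = c("TF1", "TF1", "TF1", "miR1", "miR1", "TF1", "miR2", "TF2"),
    target = c("g1", "g2", "g3", "g1", "g4", "miR1", "g9", "g9"),
    relation = c("TF-gene", "TF-gene", "TF-gene", "miRNA-gene", "miRNA-gene",
                 "TF-miRNA", "miRNA-gene", "TF-gene")))
  tests <- suppressMessages(cotarget_tests(s))
  # universe = miRNA-targeted {g1,g4,g9} intersect TF-regulated {g1,g2,g3,g9}
  row <- tests[tests$mirna == "miR1" & tests$tf == "TF1", ]
  expect_equal(row$total, 2L)  # {g1, g9}
  expect_equal(row$m, 1L)      # miR1 targets in universe: g1
  expect_equal(row$n, 1L)      # TF1 regulates in universe: g1
  expect_equal(row$x, 1L)
  expect_equal(row$p, 0.5, tolerance = 1e-12)
})

test_that("background maps override the in-store universe", {
  s <- make_store(data.frame(
    source = c("TF1", "miR1", "TF1"),
    target = c("g1", "g1", "miR1"),
    relation = c("TF-gene", "miRNA-gene", "TF-miRNA")))
  bg <- list(mirna_targets = list(miR1 = paste0("G", 1:20)),
             tf_targets = list(TF1 = paste0("G", 1:30)))
  bg$mirna_targets$miR1 <- c(bg$mirna_targets$miR1)
  tests <- suppressMessages(cotarget_tests(s, background = bg))
  expect_equal(tests$total, 20L)
  expect_equal(tests$m, 20L)
  expect_equal(tests$x, 20L)
})

test_that("merging groups by (TF, miRNA) and flattening is a bijection", {
  s <- make_store(data.frame(
    source = c("TF1", "TF1", "miR1", "miR1", "TF1", "TF2", "miR2", "miR2"),
    target = c("g1", "g2", "g1", "g2", "miR1", "g3", "g3", "TF2"),
    relation = c("TF-gene", "TF-gene", "miRNA-gene", "miRNA-gene", "TF-miRNA",
                 "TF-gene", "miRNA-gene", "miRNA-TF")))
  f3 <- enumerate_3node(s)
  merged <- merge_ffls(f3)
  expect_equal(nrow(merged), 2L)
  expect_equal(sum(merged$n_members), nrow(f3))
  pair1 <- merged[merged$tf == "TF1", ]
  expect_equal(pair1$targets, "g1;g2")
  expect_equal(pair1$ffl_class, "TF-FFL")
  flat <- flatten_merged_ffls(merged)
  expect_setequal(paste(flat$tf, flat$mirna, flat$target),
                  paste(f3$tf, f3$mirna, f3$gene))
  expect_error(merge_ffls(data.frame(a = 1)), "arity")
})

test_that("pair restriction removes FFLs of non-significant pairs", {
  store <- random_store(17, n_tf = 4, n_mirna = 4, n_gene = 8, density = 0.35)
  all3 <- enumerate_3node(store)
  expect_gte(nrow(all3), 2L)
  keep <- unique(all3[1, c("tf", "mirna")])
  restricted <- enumerate_3node(store, pairs = keep)
  expect_true(all(paste(restricted$tf, restricted$mirna) %in%
                  paste(keep$tf, keep$mirna)))
  expect_equal(nrow(restricted),
               sum(all3$tf == keep$tf & all3$mirna == keep$mirna))
})
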