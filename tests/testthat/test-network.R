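# Pair correlation sweep, database intersection, network assembly and
# export, checked against brute-force oracles and planted truth.

toy_db <- function(...) {
  target_database(data.frame(..., stringsAsFactors = FALSE))
}

test_that("correlate_pairs matches the per-pair oracle on a toy instance", {
  withr::with_seed(1, {
    mi <- matrix(rnorm(6), 2, 3, dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
    mr <- matrix(rnorm(9), 3, 3, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  })
  pairs <- correlate_pairs(mi, mr)
  expect_equal(nrow(pairs), 6)
  for (i in seq_len(nrow(pairs))) {
    ct <- cor.test(mi[pairs$mirna_id[i], ], mr[pairs$gene_id[i], ])
    expect_equal(pairs$r[i], unname(ct$estimate))
    expect_equal(pairs$p_raw[i], ct$p.value, tolerance = 1e-12)
  }
  expect_equal(pairs$p_adj, p.adjust(pairs$p_raw, "BH"))
  # perfect anti-correlation
  one <- correlate_pairs(
    matrix(c(1, 2, 3), 1, 3, dimnames = list("m", c("a", "b", "c"))),
    matrix(c(3, 2, 1), 1, 3, dimnames = list("g", c("a", "b", "c")))
  )
  expect_equal(one$r, -1)
  expect_equal(one$p_raw, 0)
})

test_that("correlate_pairs validates samples and skips degenerate features", {
  mi <- matrix(rnorm(6), 2, 3, dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
  mr <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "sX")))
  expect_error(correlate_pairs(mi, mr), "sX")
  mr2 <- rbind(
    g1 = c(1, 1, 1),
    g2 = c(1, 2, 0)
  )
  colnames(mr2) <- colnames(mi)
  expect_warning(pairs <- correlate_pairs(mi, mr2), "degenerate")
  expect_equal(sort(unique(pairs$gene_id)), "g2")
})

test_that("filter_negative_significant applies sign and inclusive threshold", {
  pairs <- data.frame(
    mirna_id = "m", gene_id = c("a", "b", "c", "d"),
    r = c(0.9, -0.9, -0.9, -0.5),
    p_raw = c(1e-6, 0.1, 1e-6, 0.03),
    p_adj = c(1e-6, 0.2, 0.05, 0.03),
    stringsAsFactors = FALSE
  )
  kept <- filter_negative_significant(pairs, 0.05)
  expect_setequal(kept$gene_id, c("c", "d")) # boundary p_adj = 0.05 included
})

test_that("database intersection is an exact set intersection with sources", {
  pairs <- data.frame(
    mirna_id = c("m1", "m1", "m2", "m2"),
    gene_id = c("g1", "g2", "g1", "g3"),
    r = -0.8, p_raw = 0.001, p_adj = 0.01, stringsAsFactors = FALSE
  )
  db1 <- toy_db(
    mirna_id = c("M1", "m2", "mX"), gene_id = c("G1", "g3", "gX"),
    source = "dbA", score = c(90, 50, 10)
  )
  db2 <- toy_db(mirna_id = "m1", gene_id = "g1", source = "dbB", score = 70)
  res <- intersect_with_databases(pairs, list(db1, db2), min_sources = 1)
  expect_setequal(
    paste(res$mirna_id, res$gene_id),
    c("m1 g1", "m2 g3") # case-folded match; m1:g2 and m2:g1 absent
  )
  m1g1 <- res[res$mirna_id == "m1", ]
  expect_equal(m1g1$n_sources, 2)
  expect_equal(m1g1$best_score, 90)
  expect_equal(m1g1$sources, "dbA,dbB")
  res2 <- intersect_with_databases(pairs, list(db1, db2), min_sources = 2)
  expect_equal(nrow(res2), 1)
  expect_error(intersect_with_databases(pairs, list()), "empty database")
})

test_that("adding a database never removes edges", {
  pairs <- data.frame(
    mirna_id = rep(sprintf("m%d", 1:4), each = 4),
    gene_id = rep(sprintf("g%d", 1:4), times = 4),
    r = -0.7, p_raw = 0.001, p_adj = 0.01, stringsAsFactors = FALSE
  )
  db1 <- toy_db(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"), source = "A")
  db2 <- toy_db(mirna_id = c("m3", "m1"), gene_id = c("g3", "g1"), source = "B")
  k1 <- intersect_with_databases(pairs, list(db1))
  k12 <- intersect_with_databases(pairs, list(db1, db2))
  expect_true(all(
    paste(k1$mirna_id, k1$gene_id) %in% paste(k12$mirna_id, k12$gene_id)
  ))
  expect_gte(nrow(k12), nrow(k1))
})

test_that("build_network deduplicates edges and exposes degrees", {
  pairs <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m2", "m1"),
    gene_id = c("g1", "g2", "g3", "g1", "g1"), # m1:g1 duplicated
    r = c(-0.9, -0.8, -0.7, -0.6, -0.9),
    p_raw = 1e-4, p_adj = 1e-3, sources = "dbA",
    stringsAsFactors = FALSE
  )
  net <- build_network(pairs)
  expect_equal(igraph::ecount(net), 4)
  deg <- degree_summary(net)
  expect_equal(deg$mirna$feature_id, c("m1", "m2"))
  expect_equal(deg$mirna$degree, c(3, 1))
  expect_equal(deg$mrna$degree[deg$mrna$feature_id == "g1"], 2)
  # star graph
  star <- build_network(data.frame(
    mirna_id = "m", gene_id = paste0("g", 1:5),
    r = -0.5, p_raw = 0.01, p_adj = 0.02, sources = "dbA",
    stringsAsFactors = FALSE
  ))
  ds <- degree_summary(star)
  expect_equal(ds$mirna$degree, 5)
  expect_equal(ds$mrna$degree, rep(1, 5))
  # empty network is a valid object
  empty <- build_network(pairs[0, ])
  expect_equal(igraph::ecount(empty), 0)
  expect_equal(nrow(degree_summary(empty)$mirna), 0)
})

test_that("fraction_of_signature_targeted computes covered counts", {
  net <- build_network(data.frame(
    mirna_id = "m", gene_id = c("g1", "g2"),
    r = -0.5, p_raw = 0.01, p_adj = 0.02, sources = "dbA",
    stringsAsFactors = FALSE
  ))
  res <- fraction_of_signature_targeted(net, c("g1", "g2"))
  expect_equal(res$fraction, 1)
  res2 <- fraction_of_signature_targeted(net, sprintf("x%d", 1:4))
  expect_equal(res2$fraction, 0)
  # the arithmetic of a partially covered signature
  res3 <- fraction_of_signature_targeted(
    net, c("g1", "g2", sprintf("x%d", 1:198))
  )
  expect_equal(res3$covered, 2)
  expect_equal(res3$fraction, 0.01)
})

test_that("network exports round-trip in every format", {
  pairs <- data.frame(
    mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
    r = c(-0.9, -0.6), p_raw = c(1e-5, 1e-3), p_adj = c(1e-4, 0.01),
    sources = c("dbA,dbB", "dbA"), stringsAsFactors = FALSE
  )
  de_i <- data.frame(feature_id = c("m1", "m2"), log2fc = c(-1.2, 2))
  expect_warning(
    net <- build_network(pairs, de_mirna = de_i),
    "log2fc undefined" # no mRNA DE table supplied
  )
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "n.sif")
  export_network(net, sif, "sif")
  expect_equal(readLines(sif), c("m1\ttargets\tg1", "m2\ttargets\tg2"))
  gml <- file.path(dir, "n.graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_setequal(
    apply(igraph::as_edgelist(back), 1, paste, collapse = "-"),
    apply(igraph::as_edgelist(net), 1, paste, collapse = "-")
  )
  expect_equal(sort(igraph::E(back)$r), sort(igraph::E(net)$r))
  tsv <- file.path(dir, "n.tsv")
  export_network(net, tsv, "edge-tsv")
  back2 <- import_network(tsv, "edge-tsv")
  expect_equal(igraph::ecount(back2), 2)
  expect_setequal(igraph::E(back2)$p_adj, igraph::E(net)$p_adj)
  # empty network writes valid files
  empty <- build_network(pairs[0, ])
  export_network(empty, sif, "sif")
  expect_equal(length(readLines(sif)), 0)
  export_network(empty, tsv, "edge-tsv")
  expect_equal(nrow(utils::read.delim(tsv)), 0)
  expect_error(export_network(net, sif, "dot"), "arg")
})

test_that("end-to-end edge set equals the triple-loop oracle", {
  withr::with_seed(55, {
    n <- 20
    mi <- matrix(rnorm(20 * n), 20, n)
    mr <- matrix(rnorm(50 * n), 50, n)
    # plant some anti-correlated pairs so the oracle set is non-trivial
    for (j in 1:15) mr[j, ] <- -mi[j, ] + rnorm(n, sd = 0.4)
    rownames(mi) <- sprintf("m%02d", 1:20)
    rownames(mr) <- sprintf("g%02d", 1:50)
    colnames(mi) <- colnames(mr) <- sprintf("s%02d", 1:n)
    db <- target_database(data.frame(
      mirna_id = sample(rownames(mi), 120, replace = TRUE),
      gene_id = sample(rownames(mr), 120, replace = TRUE),
      source = sample(c("A", "B"), 120, replace = TRUE),
      stringsAsFactors = FALSE
    ))
  })
  pairs <- correlate_pairs(mi, mr)
  kept <- intersect_with_databases(
    filter_negative_significant(pairs, 0.05), db
  )
  ours <- sort(paste(kept$mirna_id, kept$gene_id))
  oracle <- network_edge_oracle(mi, mr, db, alpha = 0.05)
  expect_identical(ours, oracle)
  expect_gt(length(oracle), 0)
})

test_that("planted pairs are recovered with perfect precision at high coupling", {
  # high-signal regime: strong coupling, deep miRNA library (members
  # measured at ~100 reads), matched (hub-free) pairs, composition-stable
  # mRNA matrix
  cfg <- quick_config(
    n_mrna = 3000, de_fraction = 50 / 3000, lib_size_mirna = 2e7,
    coupling_strength = 2.5, db_true_recall = 1, db_decoy_count = 0,
    cluster_size = 20, n_true_pairs = 20, seed = 202
  )
  ds <- generate_dataset(cfg)
  norm_i <- tmm_factors(ds$mirna_counts)
  norm_m <- tmm_factors(ds$mrna_counts)
  l2_i <- cpm(ds$mirna_counts, norm_i, log2 = TRUE)
  l2_m <- cpm(ds$mrna_counts, norm_m, log2 = TRUE)
  pairs <- correlate_pairs(
    l2_i[ds$truth$cluster_mirnas, ],
    l2_m[ds$truth$de_mrna$feature_id, ]
  )
  kept <- intersect_with_databases(
    filter_negative_significant(pairs, 0.05), ds$database
  )
  net_edges <- paste(kept$mirna_id, kept$gene_id)
  truth_edges <- paste(ds$truth$pairs$mirna_id, ds$truth$pairs$gene_id)
  expect_true(all(net_edges %in% truth_edges)) # precision 1
  expect_gte(mean(truth_edges %in% net_edges), 0.9) # recall
})
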