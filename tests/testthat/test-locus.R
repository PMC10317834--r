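# Interval membership, locus summaries, co-expression structure and sample
# clustering against planted generator structure.

mini_annotation <- function() {
  data.frame(
    feature_id = c("inL", "onChr2", "atBoundary", "noCoord", "wholeChr"),
    chrom = c("chr14", "chr2", "chr14", NA, "chr14"),
    start = c(100900000, 100900000, 100824990, NA, 5),
    end = c(100900021, 100900021, 100825010, NA, 26),
    strand = "+", stringsAsFactors = FALSE
  )
}

test_that("locus membership uses inclusive midpoints on the right chromosome", {
  locus <- parse_locus("chr14:100,825,000-101,070,000")
  expect_equal(locus$start, 100825000)
  expect_equal(locus$end, 101070000)
  expect_warning(
    members <- assign_locus_membership(mini_annotation(), locus),
    "lack coordinates"
  )
  # midpoint of atBoundary is exactly 100825000: inclusive boundary
  expect_setequal(members, c("inL", "atBoundary"))
  # whole-chromosome locus captures every feature on it
  all14 <- suppressWarnings(assign_locus_membership(
    mini_annotation(), locus_definition("chr14", 1, 3e8)
  ))
  expect_setequal(all14, c("inL", "atBoundary", "wholeChr"))
})

test_that("membership is invariant to annotation row order", {
  ds <- generate_dataset(quick_config())
  m1 <- assign_locus_membership(ds$annotation, ds$locus)
  shuffled <- ds$annotation[rev(seq_len(nrow(ds$annotation))), ]
  m2 <- assign_locus_membership(shuffled, ds$locus)
  expect_identical(m1, m2)
  # the generator's planted cluster plus its host gene are the members
  expect_setequal(m1, c(ds$truth$cluster_mirnas, ds$truth$host_gene))
})

test_that("locus_group_summary reduces to hand values on constant input", {
  l2 <- matrix(2, 3, 6, dimnames = list(
    c("m1", "m2", "m3"), paste0("s", 1:6)
  ))
  groups <- rep(c("A", "B"), each = 3)
  s <- locus_group_summary(l2, c("m1", "m2", "m3"), groups)
  expect_equal(unname(s$sample_means), rep(2, 6))
  expect_equal(unname(s$group_means[["A"]]), 2)
  expect_equal(s$tests$p_value, 1)
  # two members with values 1 and 3 average to 2
  l2b <- matrix(c(1, 3), 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  sb <- locus_group_summary(l2b, c("a", "b"), rep(c("A", "B"), 2))
  expect_equal(unname(sb$sample_means), rep(2, 4))
  expect_error(locus_group_summary(l2, "absent", groups), "no member")
})

test_that("planted gradient yields ordered group means and small Wilcoxon p", {
  ds <- generate_dataset(quick_config(cluster_size = 53, seed = 77))
  l2 <- cpm(ds$mirna_counts, tmm_factors(ds$mirna_counts), log2 = TRUE)
  s <- locus_group_summary(l2, ds$truth$cluster_mirnas, ds$metadata$group)
  gm <- s$group_means[ds$config$group_labels]
  expect_true(gm[1] > gm[2] && gm[2] > gm[3])
  # extreme-group comparison: planted shift 0 vs -0.66
  extreme <- s$tests[s$tests$group_a == "M-CLL-NS" &
    s$tests$group_b == "U-CLL-S", ]
  expect_lt(extreme$p_value, 0.01)
})

test_that("nearly all members are individually under-expressed in the low group", {
  # default settings: the condition the >0.9 fraction claim is about
  ds <- generate_dataset(synthetic_config(seed = 2))
  l2 <- cpm(ds$mirna_counts, tmm_factors(ds$mirna_counts), log2 = TRUE)
  s <- locus_group_summary(l2, ds$truth$cluster_mirnas, ds$metadata$group)
  dir <- s$member_direction[s$member_direction$group_a == "M-CLL-NS" &
    s$member_direction$group_b == "U-CLL-S", ]
  expect_gt(dir$frac_members_lower_in_b, 0.9)
})

test_that("ribbon_summary computes type-7 quantiles in genomic order", {
  l2 <- rbind(
    mA = c(1, 2, 3, 9, 9, 9),
    mB = c(5, 5, 5, 1, 2, 3)
  )
  colnames(l2) <- paste0("s", 1:6)
  ann <- data.frame(
    feature_id = c("mA", "mB"), chrom = "chr14",
    start = c(200, 100), end = c(221, 121), strand = "+",
    stringsAsFactors = FALSE
  )
  groups <- rep(c("g1", "g2"), each = 3)
  rb <- ribbon_summary(l2, ann, c("mA", "mB"), groups)
  # mB comes first (start 100)
  expect_equal(unique(rb$feature_id), c("mB", "mA"))
  row <- rb[rb$feature_id == "mA" & rb$group == "g1", ]
  expect_equal(row$median, 2)
  expect_equal(row$q25, 1.5)
  expect_equal(row$q75, 2.5)
  expect_true(all(rb$q25 <= rb$median & rb$median <= rb$q75))
  single <- ribbon_summary(
    l2[, 1, drop = FALSE], ann, c("mA", "mB"),
    factor("g1")
  )
  expect_equal(single$median, single$q25)
})

test_that("coexpression matrix is symmetric, unit-diagonal, genomically ordered", {
  ds <- generate_dataset(quick_config(seed = 13))
  l2 <- rbind(
    cpm(ds$mirna_counts, log2 = TRUE),
    cpm(ds$mrna_counts, log2 = TRUE)
  )
  cx <- coexpression_matrix(l2, ds$annotation, ds$locus, window = 5e5)
  expect_true(isSymmetric(cx$r))
  expect_equal(unname(diag(cx$r)), rep(1, nrow(cx$r)))
  ann <- ds$annotation[match(cx$feature_id, ds$annotation$feature_id), ]
  expect_true(all(diff(ann$start) > 0))
  # flanking (non-member) features are included but uncorrelated
  expect_true(any(!cx$is_member))
  flank_r <- cx$r[!cx$is_member, cx$is_member]
  expect_lt(mean(abs(flank_r)), 0.35)
  # duplicated feature correlates perfectly
  l2dup <- rbind(l2, DUP = l2[ds$truth$cluster_mirnas[1], ])
  ann2 <- rbind(ds$annotation, data.frame(
    feature_id = "DUP", chrom = "chr14", start = 100900001,
    end = 100900022, strand = "+", type = "miRNA"
  ))
  cx2 <- coexpression_matrix(l2dup, ann2, ds$locus)
  expect_equal(cx2$r["DUP", ds$truth$cluster_mirnas[1]], 1)
})

test_that("strong shared factor produces strong within-cluster correlation", {
  ds <- generate_dataset(quick_config(
    cluster_factor_sd = 1.5, seed = 19, n_true_pairs = 0
  ))
  l2 <- cpm(ds$mirna_counts, log2 = TRUE)
  mem <- ds$truth$cluster_mirnas
  r <- cor(t(l2[mem, ]))
  expect_gt(median(r[upper.tri(r)]), 0.7)
  # independent features stay near zero
  others <- setdiff(rownames(l2), mem)[1:20]
  r0 <- cor(t(l2[others, ]))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.25)
})

test_that("locus mean correlates with the host gene at default coupling", {
  r_host <- vapply(23:25, function(s) {
    ds <- generate_dataset(quick_config(cluster_size = 53, seed = s))
    l2_i <- cpm(ds$mirna_counts, log2 = TRUE)
    l2_m <- cpm(ds$mrna_counts, log2 = TRUE)
    sm <- locus_group_summary(l2_i, ds$truth$cluster_mirnas, ds$metadata$group)
    locus_vs_gene_correlation(
      sm$sample_means, l2_m[ds$truth$host_gene, ]
    )$estimate
  }, numeric(1))
  expect_gt(mean(r_host), 0.8)
  # self-correlation and anti-correlation sanity
  ds <- generate_dataset(quick_config(seed = 23))
  l2_i <- cpm(ds$mirna_counts, log2 = TRUE)
  s <- locus_group_summary(l2_i, ds$truth$cluster_mirnas, ds$metadata$group)
  expect_equal(
    locus_vs_gene_correlation(s$sample_means, s$sample_means)$estimate, 1
  )
  expect_equal(
    locus_vs_gene_correlation(s$sample_means, 3 - s$sample_means)$estimate, -1
  )
})

test_that("cluster_samples recovers well-separated groups and is deterministic", {
  # three groups of samples with locus means 3/2/1 and tiny noise
  withr::with_seed(31, {
    l2 <- cbind(
      matrix(rnorm(20 * 5, 3, 0.05), 20, 5),
      matrix(rnorm(20 * 5, 2, 0.05), 20, 5),
      matrix(rnorm(20 * 5, 1, 0.05), 20, 5)
    )
  })
  rownames(l2) <- paste0("m", 1:20)
  colnames(l2) <- paste0("s", 1:15)
  groups <- rep(c("gHigh", "gMid", "gLow"), each = 5)
  cl <- cluster_samples(l2, rownames(l2), groups, k = 3, seed = 4)
  expect_equal(unname(as.character(cl$assignment[1:5])), rep("high", 5))
  expect_equal(unname(as.character(cl$assignment[6:10])), rep("intermediate", 5))
  expect_equal(unname(as.character(cl$assignment[11:15])), rep("low", 5))
  expect_equal(unname(cl$contingency["gHigh", "high"]), 5)
  cl2 <- cluster_samples(l2, rownames(l2), groups, k = 3, seed = 4)
  expect_identical(cl$assignment, cl2$assignment)
  k1 <- cluster_samples(l2, rownames(l2), groups, k = 1, seed = 4)
  expect_equal(length(unique(k1$assignment)), 1)
})

test_that("optional Fisher test on the cluster contingency is available", {
  withr::with_seed(31, {
    l2 <- cbind(
      matrix(rnorm(20 * 5, 3, 0.05), 20, 5),
      matrix(rnorm(20 * 5, 1, 0.05), 20, 5)
    )
  })
  rownames(l2) <- paste0("m", 1:20)
  colnames(l2) <- paste0("s", 1:10)
  groups <- rep(c("gHigh", "gLow"), each = 5)
  cl <- cluster_samples(l2, rownames(l2), groups, k = 2, seed = 4, fisher = TRUE)
  expect_lt(cl$fisher_p, 0.05) # perfectly separated groups
  expect_null(cluster_samples(l2, rownames(l2), groups, k = 2, seed = 4)$fisher_p)
})
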