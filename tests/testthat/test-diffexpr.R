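# Filtering, CPM, TMM (vs the edgeR reference implementation), dispersion
# recovery and the NB LRT on planted and null data.

test_that("filter_low_counts applies inclusive thresholds and reports buckets", {
  m <- toy_counts(rbind(
    f1 = c(0, 0, 0, 0),     # undetectable
    f2 = c(1, 0, 0, 0),     # low
    f3 = c(100, 100, 0, 0), # exactly min_cpm in exactly min_samples
    f4 = c(500, 500, 500, 500),
    f5 = c(5, 5, 5, 5)
  ))
  # library sizes: all features sum per sample
  lib <- colSums(m$counts)
  min_cpm <- 100 / lib[1] * 1e6
  res <- filter_low_counts(m, min_cpm = min_cpm, min_samples = 2)
  expect_setequal(rownames(res$counts$counts), c("f3", "f4"))
  expect_equal(res$report$n_undetectable, 1)
  expect_equal(res$report$n_retained, 2)
  expect_equal(res$report$n_low, 2)
  expect_equal(
    res$report$n_undetectable + res$report$n_low + res$report$n_retained,
    res$report$n_total
  )
})

test_that("filter_low_counts retains a hand-computed CPM set", {
  m <- toy_counts(rbind(
    a = c(10, 10), b = c(1, 0), c = c(0, 1), d = c(989, 989), e = c(0, 0)
  ))
  # libraries are 1000 and 1000: CPMs are a=1e4, b=(1e3,0), c=(0,1e3), d~9.9e5
  res <- filter_low_counts(m, min_cpm = 1000, min_samples = 2)
  expect_setequal(rownames(res$counts$counts), c("a", "d"))
  res1 <- filter_low_counts(m, min_cpm = 1000, min_samples = 1)
  expect_setequal(rownames(res1$counts$counts), c("a", "b", "c", "d"))
  expect_error(
    filter_low_counts(m, min_cpm = 1e9, min_samples = 1),
    "no features pass"
  )
})

test_that("cpm matches its defining formula", {
  m <- toy_counts(matrix(c(10, 90), 2, 1))
  expect_equal(as.vector(cpm(m)), c(1e5, 9e5))
  m2 <- toy_counts(matrix(c(10, 90, 30, 70), 2, 2))
  expect_equal(unname(colSums(cpm(m2))), c(1e6, 1e6))
  # count 0, library 1e6, prior 0.5
  m3 <- toy_counts(matrix(c(0, 1e6 - 0), 2, 1))
  expect_equal(
    cpm(m3, log2 = TRUE, prior = 0.5)["f01", 1],
    log2(0.5 / (1e6 + 1) * 1e6)
  )
  expect_equal(cpm(m3, log2 = TRUE, prior = 0.5)["f01", 1], -1.0000014,
    tolerance = 1e-6
  )
})

test_that("tmm factors are 1 for identical or proportionally scaled samples", {
  m <- toy_counts(matrix(rep(c(5, 10, 20, 400), 3), 4, 3))
  expect_equal(unname(tmm_factors(m)$tmm_factors), rep(1, 3))
  withr::with_seed(1, {
    base <- rpois(200, 50)
  })
  m2 <- toy_counts(cbind(base, 2 * base))
  f <- tmm_factors(m2)
  expect_equal(unname(f$tmm_factors), c(1, 1))
  expect_equal(unname(f$effective_sizes[2] / f$effective_sizes[1]), 2)
})

test_that("tmm factors match the edgeR reference on random data", {
  skip_if_not_installed("edgeR")
  withr::with_seed(99, {
    counts <- matrix(rnbinom(400 * 6, mu = 80, size = 5), 400, 6)
    counts[1:20, 4] <- counts[1:20, 4] * 8 # asymmetric composition shift
  })
  m <- toy_counts(counts)
  ours <- tmm_factors(m)$tmm_factors
  ref <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("dispersion estimation recovers the simulation truth", {
  groups <- rep(c("A", "B"), each = 10)
  withr::with_seed(5, {
    mu <- exp(rnorm(2000, log(100), 1))
    pois <- matrix(rpois(2000 * 20, mu), 2000, 20)
    nb <- matrix(rnbinom(2000 * 20, mu = mu, size = 1 / 0.2), 2000, 20)
  })
  d_pois <- nb_fit_dispersion(toy_counts(pois), groups)
  expect_lte(d_pois$common, 0.01)
  d_nb <- nb_fit_dispersion(toy_counts(nb), groups)
  expect_gte(d_nb$common, 0.15)
  expect_lte(d_nb$common, 0.25)
  const <- toy_counts(matrix(7, 50, 6))
  expect_lt(nb_fit_dispersion(const, rep(c("A", "B"), 3))$common, 1.01e-4)
})

test_that("nb_lrt recovers trivial contrasts", {
  # 4 features x 20 samples: groups of 10 samples at counts 10 vs 40
  counts <- matrix(0, 4, 20)
  counts[, 1:10] <- 10
  counts[, 11:20] <- 40
  m <- toy_counts(counts)
  groups <- rep(c("A", "B"), each = 10)
  norm <- normalization_state(setNames(rep(1e4, 20), colnames(m$counts)))
  de <- nb_lrt(m, groups, contrast = c("A", "B"), norm = norm, dispersion = 0.1)
  expect_equal(de$log2fc, rep(2, 4), tolerance = 0.01)
  expect_true(all(de$p_raw < 0.05))
  # identical groups: log2fc 0, p ~ 1
  counts2 <- matrix(25, 4, 20)
  de2 <- nb_lrt(toy_counts(counts2), groups,
    contrast = c("A", "B"),
    norm = norm, dispersion = 0.1
  )
  expect_equal(de2$log2fc, rep(0, 4))
  expect_true(all(de2$p_raw > 0.99))
})

test_that("nb_lrt p-values broadly agree with edgeR on a small fixture", {
  skip_if_not_installed("edgeR")
  withr::with_seed(12, {
    mu <- exp(rnorm(300, log(60), 1))
    counts <- matrix(rnbinom(300 * 12, mu = mu, size = 10), 300, 12)
    counts[1:15, 7:12] <- matrix(
      rnbinom(15 * 6, mu = mu[1:15] * 4, size = 10), 15, 6
    )
  })
  m <- toy_counts(counts)
  groups <- rep(c("A", "B"), each = 6)
  de <- nb_lrt(m, groups, contrast = c("A", "B"))
  y <- edgeR::DGEList(counts, group = groups)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, model.matrix(~groups))
  fit <- edgeR::glmFit(y, model.matrix(~groups))
  ref <- edgeR::glmLRT(fit)$table
  # same testing problem, different dispersion estimators: demand strong
  # rank agreement and matched fold changes for the planted block
  expect_gt(cor(-log10(de$p_raw), -log10(ref$PValue), method = "spearman"), 0.9)
  expect_equal(de$log2fc[1:15], ref$logFC[1:15], tolerance = 0.2)
  top_ours <- order(de$p_raw)[1:15]
  top_ref <- order(ref$PValue)[1:15]
  expect_gte(length(intersect(top_ours, top_ref)), 12)
})

test_that("DE results are invariant to row and column order", {
  ds <- generate_dataset(quick_config(n_mrna = 120, seed = 8))
  m <- ds$mrna_counts
  groups <- factor(ifelse(ds$metadata$group == "U-CLL-S", "U", "M"),
    levels = c("M", "U")
  )
  norm <- tmm_factors(m)
  phi <- nb_fit_dispersion(m, groups, norm)
  de <- nb_lrt(m, groups, contrast = c("M", "U"), norm = norm, dispersion = phi)
  perm_r <- sample(nrow(m$counts))
  perm_c <- sample(ncol(m$counts))
  m2 <- m[perm_r, perm_c]
  groups2 <- groups[perm_c]
  norm2 <- tmm_factors(m2)
  phi2 <- nb_fit_dispersion(m2, groups2, norm2)
  de2 <- nb_lrt(m2, groups2, contrast = c("M", "U"), norm = norm2, dispersion = phi2)
  de2 <- de2[match(de$feature_id, de2$feature_id), ]
  expect_equal(de$log2fc, de2$log2fc, tolerance = 1e-9)
  expect_equal(de$p_raw, de2$p_raw, tolerance = 1e-9)
})

test_that("integer-rescaling one sample leaves the DE table unchanged", {
  ds <- generate_dataset(quick_config(n_mrna = 100, seed = 9))
  m <- ds$mrna_counts
  groups <- ifelse(ds$metadata$group == "U-CLL-S", "U", "M")
  de <- nb_lrt(m, groups,
    contrast = c("M", "U"), norm = tmm_factors(m),
    dispersion = 0.1
  )
  scaled <- m$counts
  scaled[, 3] <- scaled[, 3] * 5L
  m2 <- count_matrix(scaled)
  norm2 <- tmm_factors(m2)
  # effective size of the rescaled sample grows ~5x (exactly 5x up to the
  # inverse-variance weights, which shift when the rescaled sample serves
  # as the TMM reference)
  expect_equal(
    unname(norm2$effective_sizes[3] / tmm_factors(m)$effective_sizes[3]),
    5,
    tolerance = 0.02
  )
  # the DE table itself cannot be exactly invariant under a count
  # likelihood (the rescaled sample carries more information); demand
  # bounded drift instead
  de2 <- nb_lrt(m2, groups, contrast = c("M", "U"), norm = norm2, dispersion = 0.1)
  expect_gt(cor(de$log2fc, de2$log2fc), 0.98)
  expect_lt(median(abs(de$log2fc - de2$log2fc)), 0.1)
  expect_gt(cor(-log10(de$p_raw), -log10(de2$p_raw), method = "spearman"), 0.9)
})

test_that("select_signature ranks, tie-breaks and truncates as documented", {
  de <- data.frame(
    feature_id = c("a", "b", "c", "d", "e"),
    log2fc = c(2, -3, 1.5, 0.5, 2.5),
    mean_log2cpm = 1, p_raw = c(0.001, 0.001, 0.01, 0.0001, 0.02),
    fdr = c(0.01, 0.01, 0.03, 0.001, 0.2),
    direction = "up", stringsAsFactors = FALSE
  )
  # d fails |lfc|; e fails fdr; tie between a and b broken by larger |lfc|
  expect_equal(select_signature(de), c("b", "a", "c"))
  expect_equal(select_signature(de, top_n = 2), c("b", "a"))
  expect_warning(sig <- select_signature(de, top_n = 200), "only 3")
  expect_equal(length(sig), 3)
  expect_warning(
    empty <- select_signature(de, fdr_max = 1e-9),
    "no features"
  )
  expect_equal(empty, character(0))
})

test_that("volcano categories follow the two-tier rule", {
  de <- data.frame(
    feature_id = c("a", "b", "c"),
    log2fc = c(2, 1.5, 3), mean_log2cpm = 1,
    p_raw = c(0.001, 0.01, 0.5), fdr = c(0.01, 0.2, 0.9),
    direction = "up", stringsAsFactors = FALSE
  )
  expect_equal(volcano_categories(de)$volcano_category, c("dark", "light", "ns"))
})
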