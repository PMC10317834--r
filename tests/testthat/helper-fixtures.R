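# Shared fixtures and independent oracles. Test datasets are scaled-down
# configurations of the synthetic generator (fewer features, smaller
# libraries) with the planted structure left at its defaults.

quick_config <- function(...) {
  defaults <- list(
    n_per_group = 13, n_mrna = 400, n_mirna = 120,
    lib_size_mrna = 4e7, lib_size_mirna = 2.4e6,
    cluster_size = 20, n_true_pairs = 40,
    de_fraction = 0.1, db_decoy_count = 500, seed = 42
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

toy_counts <- function(mat, feature_type = "mRNA") {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("f%02d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  }
  count_matrix(mat, feature_type)
}

# --- independent oracles ---------------------------------------------------

# O(m^2) brute-force BH: adj_i = min over all j with p_j >= p_i (by sorted
# order) of p_(j) * m / j, computed without the cummin recursion.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranks <- match(seq_len(m), o)
  vapply(seq_len(m), function(i) {
    ri <- which(o == i)
    min(1, min(vapply(ri:m, function(j) p[o[j]] * m / j, numeric(1))))
  }, numeric(1))
}

# Exact rank-sum p by literal enumeration of all group assignments.
rank_sum_oracle <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  u_stat <- function(idx) {
    aa <- pooled[idx]
    bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  obs <- u_stat(seq_len(n_a))
  all_u <- apply(utils::combn(n, n_a), 2, u_stat)
  lower <- mean(all_u <= obs + 1e-9)
  upper <- mean(all_u >= obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Exact signed-rank p by literal enumeration of all sign patterns.
signed_rank_oracle <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  all_v <- as.vector(signs %*% r)
  lower <- mean(all_v <= obs + 1e-9)
  upper <- mean(all_v >= obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Triple-loop edge-set oracle: {(m, g): r < 0, p_adj <= alpha, (m, g) in db}.
network_edge_oracle <- function(mirna_l2, mrna_l2, dbs, alpha = 0.05) {
  db_keys <- character(0)
  if (inherits(dbs, "target_database")) dbs <- list(dbs)
  for (d in dbs) {
    db_keys <- c(db_keys, paste(tolower(d$mirna_id), tolower(d$gene_id)))
  }
  rs <- c()
  ps <- c()
  keys <- c()
  for (m in rownames(mirna_l2)) {
    for (g in rownames(mrna_l2)) {
      ct <- stats::cor.test(mirna_l2[m, ], mrna_l2[g, ])
      rs <- c(rs, unname(ct$estimate))
      ps <- c(ps, ct$p.value)
      keys <- c(keys, paste(m, g))
    }
  }
  adj <- stats::p.adjust(ps, method = "BH")
  sort(keys[rs < 0 & adj <= alpha & tolower(keys) %in% db_keys])
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
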