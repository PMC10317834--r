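#' @importFrom stats pt pnorm pchisq pwilcox dwilcox psignrank var sd
#'   quantile median rnorm rbinom rnbinom rpois runif optimize setNames cor
NULL

test_result <- function(statistic, p_value, method, n,
                        estimate = NULL, degenerate = FALSE, extra = list()) {
  structure(
    c(list(
      statistic = statistic, p_value = p_value, method = method,
      n = n, estimate = estimate, degenerate = degenerate
    ), extra),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %s, p = %s%s\n", x$method,
    format(x$statistic), format(x$p_value),
    if (isTRUE(x$degenerate)) " (degenerate)" else ""
  ))
  if (!is.null(x$estimate)) cat(sprintf("  estimate = %s\n", format(x$estimate)))
  invisible(x)
}

#' Pearson correlation with a t-based p-value
#'
#' Computes the sample Pearson correlation and its two-sided p-value from the
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. A zero-variance input yields a flagged degenerate result (`r` and
#' `p` are `NA`) rather than an error, so matrix-scale sweeps can proceed.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `test_result` with `estimate` = r.
#' @examples
#' pearson_corr(c(1, 2, 3), c(3, 2, 1))$estimate # -1
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    return(test_result(NA_real_, NA_real_, "Pearson correlation", n,
      estimate = NA_real_, degenerate = TRUE
    ))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
    tstat <- sign(r) * Inf
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  test_result(tstat, p, "Pearson correlation", n, estimate = r)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `adj_(i) = min_(j >= i) p_(j) * m / j`, capped at
#' 1 and returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.9)) # 0.03 0.06 0.90
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# Exact two-sided tail of the Mann-Whitney U distribution: 2 * min(tails),
# capped at 1 (the package-wide exact two-sided convention).
exact_u_pvalue <- function(u, n_a, n_b) {
  lower <- pwilcox(u, n_a, n_b)
  upper <- if (u >= 1) 1 - pwilcox(u - 1, n_a, n_b) else 1
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided comparison of two independent samples. Exact mode computes the
#' tail of the Mann-Whitney U statistic over all `choose(n_a + n_b, n_a)`
#' group assignments (feasible for both n <= 25 and no ties); with ties, or
#' in `approx` mode, a normal approximation with midranks, tie-corrected
#' variance and continuity correction is used. Requesting `exact` with ties
#' falls back to the approximation with a warning.
#'
#' @param a,b Numeric vectors (each length >= 1).
#' @param mode One of `"auto"`, `"exact"`, `"approx"`.
#' @return A `test_result`; `statistic` is the Mann-Whitney U of `a`
#'   (exact) or the z value (approx); `n` is `c(n_a, n_b)`; for exact tests
#'   the number of enumerated assignments is reported as `n_enumerated`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  n_a <- length(a)
  n_b <- length(b)
  pooled <- c(a, b)
  has_ties <- anyDuplicated(pooled) > 0
  want_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = n_a <= 25 && n_b <= 25
  )
  if (want_exact && has_ties) {
    if (mode == "exact") {
      warning("ties present: falling back to normal approximation")
    }
    want_exact <- FALSE
  }
  r <- rank(pooled)
  w_a <- sum(r[seq_len(n_a)])
  u <- w_a - n_a * (n_a + 1) / 2
  if (want_exact) {
    p <- exact_u_pvalue(u, n_a, n_b)
    return(test_result(u, p, "Wilcoxon rank-sum (exact)", c(n_a, n_b),
      extra = list(n_enumerated = choose(n_a + n_b, n_a))
    ))
  }
  n <- n_a + n_b
  mu <- n_a * n_b / 2
  ties <- table(pooled)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(test_result(0, 1, "Wilcoxon rank-sum (normal approx)",
      c(n_a, n_b),
      degenerate = TRUE
    ))
  }
  diff <- u - mu
  z <- (diff - sign(diff) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  test_result(z, p, "Wilcoxon rank-sum (normal approx)", c(n_a, n_b))
}

# Distribution of 2*V (integer-valued) over all sign patterns for midranks r:
# dynamic-programming convolution; returns P(V >= v) and P(V <= v).
signed_rank_tail_enum <- function(ranks2, v2) {
  total <- sum(ranks2)
  freq <- numeric(total + 1) # index = value of 2V, offset 1
  freq[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), freq[seq_len(total + 1 - r)])
    freq <- freq + shifted
  }
  freq <- freq / sum(freq)
  vals <- 0:total
  c(
    lower = sum(freq[vals <= v2 + 1e-9]),
    upper = sum(freq[vals >= v2 - 1e-9])
  )
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests symmetry of `x` about `mu`, two-sided. Zero differences are dropped
#' (their count is reported). Without ties among the absolute differences and
#' effective n <= 25 the exact signed-rank distribution is used; with ties
#' and effective n <= 15 all `2^n` sign patterns are enumerated with
#' midranks; otherwise a tie-corrected normal approximation with continuity
#' correction applies. If every difference is zero, the result is degenerate
#' with p = 1.
#'
#' @param x Numeric vector (length >= 1).
#' @param mu Null centre of symmetry.
#' @return A `test_result`; `statistic` is the positive-rank sum V; extras
#'   report `n_zero` (dropped) and, for exact paths, `n_enumerated`.
#' @examples
#' wilcoxon_signed_rank(c(1.5, 1.6, 1.7, 1.8, 1.9), mu = 1)$p_value # 0.0625
#' @export
wilcoxon_signed_rank <- function(x, mu = 0) {
  if (length(x) < 1) stop("x must be non-empty")
  d <- x - mu
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(test_result(0, 1, "Wilcoxon signed-rank", 0,
      degenerate = TRUE, extra = list(n_zero = n_zero)
    ))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= 25) {
    lower <- psignrank(v, n)
    upper <- if (v >= 1) 1 - psignrank(v - 1, n) else 1
    p <- min(1, 2 * min(lower, upper))
    return(test_result(v, p, "Wilcoxon signed-rank (exact)", n,
      extra = list(n_zero = n_zero, n_enumerated = 2^n)
    ))
  }
  if (has_ties && n <= 15) {
    tails <- signed_rank_tail_enum(as.integer(round(2 * r)), 2 * v)
    p <- min(1, 2 * min(tails["lower"], tails["upper"]))
    return(test_result(v, p, "Wilcoxon signed-rank (exact, midranks)", n,
      extra = list(n_zero = n_zero, n_enumerated = 2^n)
    ))
  }
  mu_v <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(test_result(v, 1, "Wilcoxon signed-rank (normal approx)", n,
      degenerate = TRUE, extra = list(n_zero = n_zero)
    ))
  }
  diff <- v - mu_v
  z <- (diff - sign(diff) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  test_result(v, p, "Wilcoxon signed-rank (normal approx)", n,
    extra = list(n_zero = n_zero, z = z)
  )
}

#' One-sample Student t-test
#'
#' @param x Numeric vector, length >= 2.
#' @param mu Null mean.
#' @param alternative `"two.sided"`, `"greater"` (mean > mu) or `"less"`.
#' @return A `test_result`; zero sample variance yields a degenerate result
#'   (`p = NA`) so callers can substitute an empirical p-value.
#' @examples
#' one_sample_t(c(2, 4), mu = 0, alternative = "greater")$p_value # 0.1024
#' @export
one_sample_t <- function(x, mu = 0,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  s <- sd(x)
  if (s == 0) {
    return(test_result(NA_real_, NA_real_, "One-sample t", n,
      estimate = mean(x), degenerate = TRUE
    ))
  }
  tstat <- (mean(x) - mu) / (s / sqrt(n))
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(tstat), n - 1),
    greater = pt(tstat, n - 1, lower.tail = FALSE),
    less = pt(tstat, n - 1)
  )
  test_result(tstat, p, sprintf("One-sample t (%s)", alternative), n,
    estimate = mean(x)
  )
}

kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1, ] <- points[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((points - matrix(centers[1, ], n, ncol(points), byrow = TRUE))^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- points[sample.int(n, 1, prob = probs), ]
      d2 <- pmin(d2, rowSums(
        (points - matrix(centers[j, ], n, ncol(points), byrow = TRUE))^2
      ))
    }
  }
  centers
}

lloyd_once <- function(points, k, max_iter = 100) {
  n <- nrow(points)
  centers <- kmeanspp_init(points, k)
  assign_prev <- rep(0L, n)
  inertia_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- sapply(seq_len(k), function(j) {
      rowSums((points - matrix(centers[j, ], n, ncol(points), byrow = TRUE))^2)
    })
    d2 <- matrix(d2, n, k)
    assign <- max.col(-d2, ties.method = "first")
    # empty cluster: re-seed its center from the point farthest from its
    # current assigned center
    for (j in seq_len(k)) {
      if (!any(assign == j)) {
        far <- which.max(d2[cbind(seq_len(n), assign)])
        centers[j, ] <- points[far, ]
        assign[far] <- j
      }
    }
    inertia_trace <- c(
      inertia_trace,
      sum(rowSums((points - centers[assign, , drop = FALSE])^2))
    )
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(points[assign == j, , drop = FALSE])
    }
    if (all(assign == assign_prev)) break
    assign_prev <- assign
  }
  inertia <- sum(rowSums((points - centers[assign, , drop = FALSE])^2))
  list(
    assignment = assign, centers = centers, inertia = inertia,
    inertia_trace = c(inertia_trace, inertia), iterations = iter
  )
}

#' K-means clustering (Lloyd's algorithm with k-means++ seeding)
#'
#' Best-of-restarts Lloyd iteration, deterministic given `seed`. Clusters are
#' relabelled by descending centre mean so that cluster 1 is always the
#' "high" cluster; an empty cluster encountered during iteration is re-seeded
#' from the point farthest from its assigned centre.
#'
#' @param points Numeric matrix (items x dims).
#' @param k Number of clusters, `k <= nrow(points)`.
#' @param restarts Number of independent k-means++ restarts.
#' @param seed Integer seed controlling all randomness.
#' @return A list with `assignment` (integer vector, labels ordered by
#'   descending centre mean), `centers`, `inertia`, `inertia_trace` (of the
#'   best restart) and `iterations`.
#' @export
kmeans_pp <- function(points, k, restarts = 10, seed = 1) {
  points <- as.matrix(points)
  if (k > nrow(points)) stop("k must not exceed the number of items")
  if (k < 1) stop("k must be >= 1")
  best <- withr::with_seed(seed, {
    fits <- lapply(seq_len(restarts), function(i) lloyd_once(points, k))
    fits[[which.min(vapply(fits, `[[`, numeric(1), "inertia"))]]
  })
  # deterministic high/intermediate/low semantics: order by center mean
  ord <- order(rowMeans(best$centers), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  best$assignment <- relabel[best$assignment]
  best$centers <- best$centers[ord, , drop = FALSE]
  best
}

#' Principal component analysis by column-centred SVD
#'
#' Columns are centred (not scaled); the sign of each component is fixed so
#' that its largest-magnitude loading is positive. Variance explained is
#' relative to the total variance of the centred matrix, so the reported
#' values sum to at most 1.
#'
#' @param x Numeric matrix (samples x features).
#' @param n_components Number of components,
#'   `<= min(nrow(x) - 1, ncol(x))`.
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components) and `var_explained`.
#' @export
pca_svd <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (n_components > min(nrow(x) - 1, ncol(x))) {
    stop("n_components must be <= min(samples - 1, features)")
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- svd(xc, nu = n_components, nv = n_components)
  d <- s$d[seq_len(n_components)]
  total <- sum(s$d^2)
  ve <- if (total > 0) d^2 / total else rep(0, n_components)
  scores <- s$u %*% diag(d, n_components)
  loadings <- s$v
  for (j in seq_len(n_components)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  list(scores = scores, loadings = loadings, var_explained = ve)
}
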