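# Negative-binomial (NB2) machinery for the differential expression stage.
# Parameterization throughout: var = mu + phi * mu^2, i.e. size = 1/phi.

nb_loglik <- function(y, mu, phi) {
  if (phi <= 0) return(sum(stats::dpois(y, lambda = mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# MLE of a single log-rate beta for y ~ NB(exp(beta) * eff, phi), by Newton
# with an optimize() fallback. Returns the maximized log-likelihood.
nb_fit_group <- function(y, eff, phi) {
  if (sum(y) == 0) return(0) # likelihood -> 1 as mu -> 0
  r <- 1 / phi
  beta <- log(sum(y) / sum(eff))
  ok <- FALSE
  for (iter in 1:50) {
    mu <- exp(beta) * eff
    score <- sum(y - mu * (y + r) / (mu + r))
    hess <- -sum((y + r) * r * mu / (mu + r)^2)
    if (!is.finite(score) || !is.finite(hess) || hess >= 0) break
    step <- score / hess
    step <- max(-2, min(2, step)) # damped
    beta <- beta - step
    if (abs(step) < 1e-10) {
      ok <- TRUE
      break
    }
  }
  if (!ok) {
    b0 <- log(sum(y) / sum(eff))
    beta <- optimize(
      function(b) nb_loglik(y, exp(b) * eff, phi),
      interval = b0 + c(-10, 10), maximum = TRUE, tol = 1e-9
    )$maximum
  }
  nb_loglik(y, exp(beta) * eff, phi)
}

#' Estimate negative-binomial dispersion
#'
#' A common dispersion is found by maximizing the NB profile likelihood over
#' a log-spaced phi grid (group means plugged in from normalised group
#' totals), then refined by golden-section search. Per-feature
#' method-of-moments estimates are shrunk toward the common value with a
#' fixed prior weight: `phi_f = (w0 * phi_common + df * phi_mom) / (w0 + df)`
#' with `w0 = 20` prior degrees of freedom and `df = n_samples - n_groups`.
#' Estimates are floored at 1e-4.
#'
#' @param m A `count_matrix` or bare counts matrix.
#' @param groups Factor (or coercible) of group labels, one per sample.
#' @param norm Optional `normalization_state`; defaults to library sizes.
#' @param prior_weight Prior degrees of freedom for shrinkage.
#' @return List with `common` (scalar) and `per_feature` (named vector).
#' @export
nb_fit_dispersion <- function(m, groups, norm = NULL, prior_weight = 20) {
  m <- as_count_matrix(m)
  counts <- m$counts
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) stop("groups must match samples")
  eff <- if (is.null(norm)) colSums(counts) else norm$effective_sizes[colnames(counts)]
  # plug-in group means: mu_fs = q_fg * eff_s with q from normalised totals
  mu <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (g in levels(groups)) {
    sel <- groups == g
    q <- rowSums(counts[, sel, drop = FALSE]) / sum(eff[sel])
    mu[, sel] <- q %o% eff[sel]
  }
  prof <- function(phi) {
    pos <- mu > 0
    sum(stats::dnbinom(counts[pos], size = 1 / phi, mu = mu[pos], log = TRUE))
  }
  grid <- 10^seq(-4, 0.7, length.out = 25)
  ll <- vapply(grid, prof, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  common <- optimize(function(lp) prof(exp(lp)),
    interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-4
  )$maximum
  common <- max(1e-4, exp(common))
  # per-feature method of moments on rates z = y / eff:
  # Var(z) = q/eff + phi q^2, pooled within groups
  z <- t(t(counts) / eff)
  num <- 0
  den <- 0
  for (g in levels(groups)) {
    sel <- groups == g
    ng <- sum(sel)
    if (ng < 2) next
    zg <- z[, sel, drop = FALSE]
    qg <- rowMeans(zg)
    vg <- apply(zg, 1, var)
    shot <- qg * mean(1 / eff[sel])
    num <- num + (ng - 1) * pmax(0, vg - shot)
    den <- den + (ng - 1) * qg^2
  }
  phi_mom <- ifelse(den > 0, num / den, common)
  df <- ncol(counts) - nlevels(groups)
  per_feature <- (prior_weight * common + df * phi_mom) / (prior_weight + df)
  per_feature <- pmax(1e-4, per_feature)
  names(per_feature) <- rownames(counts)
  list(common = common, per_feature = per_feature)
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' Per feature, an NB model with log link and offset `log(effective size)`
#' is fitted under the full model (one mean per group) and the null
#' (a single mean); the LRT statistic `2 * (l_full - l_null)` is referred to
#' a chi-squared distribution with 1 df. Fold change is moderated by a prior
#' count added to each group total so that zero groups yield finite
#' estimates: `log2fc = log2(q_alt / q_ref)` with
#' `q_g = (sum counts_g + prior) / (sum effective sizes_g)`.
#' BH adjustment is applied over all tested features.
#'
#' @param m A `count_matrix` or bare counts matrix.
#' @param groups Two-level factor of group labels (>= 2 samples each).
#' @param contrast Character of length 2, `c(ref, alt)`; `log2fc` is alt
#'   relative to ref. Defaults to the factor level order.
#' @param norm Optional `normalization_state`.
#' @param dispersion Per-feature dispersion vector, a scalar, or the result
#'   of [nb_fit_dispersion()] (its `per_feature` slot is used). When missing,
#'   dispersion is estimated internally.
#' @param prior Prior count for fold-change moderation.
#' @return A `data.frame` (DE table) with columns `feature_id`, `log2fc`,
#'   `mean_log2cpm`, `p_raw`, `fdr`, `direction` (`up`/`down`/`ns` at
#'   FDR <= 0.05 and |log2fc| >= 1).
#' @export
nb_lrt <- function(m, groups, contrast = NULL, norm = NULL,
                   dispersion = NULL, prior = 0.5) {
  m <- as_count_matrix(m)
  counts <- m$counts
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) stop("groups must match samples")
  if (nlevels(droplevels(groups)) != 2) stop("groups must have exactly 2 levels")
  groups <- droplevels(groups)
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  if (is.null(contrast)) contrast <- levels(groups)
  if (!all(contrast %in% levels(groups)) || length(contrast) != 2) {
    stop("contrast must name the two group levels as c(ref, alt)")
  }
  eff <- if (is.null(norm)) colSums(counts) else norm$effective_sizes[colnames(counts)]
  if (is.null(dispersion)) dispersion <- nb_fit_dispersion(m, groups, norm)
  phi <- if (is.list(dispersion)) dispersion$per_feature else dispersion
  if (length(phi) == 1) phi <- rep(phi, nrow(counts))
  phi <- pmax(1e-4, phi)

  sel_ref <- groups == contrast[1]
  sel_alt <- groups == contrast[2]
  q_ref <- (rowSums(counts[, sel_ref, drop = FALSE]) + prior) / sum(eff[sel_ref])
  q_alt <- (rowSums(counts[, sel_alt, drop = FALSE]) + prior) / sum(eff[sel_alt])
  log2fc <- log2(q_alt / q_ref)

  nfeat <- nrow(counts)
  p_raw <- numeric(nfeat)
  for (f in seq_len(nfeat)) {
    y <- counts[f, ]
    l_full <- nb_fit_group(y[sel_ref], eff[sel_ref], phi[f]) +
      nb_fit_group(y[sel_alt], eff[sel_alt], phi[f])
    l_null <- nb_fit_group(y, eff, phi[f])
    stat <- max(0, 2 * (l_full - l_null))
    p_raw[f] <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  fdr <- bh_adjust(p_raw)
  mean_log2cpm <- rowMeans(cpm(m, norm = norm, log2 = TRUE, prior = prior))
  direction <- ifelse(
    fdr <= 0.05 & abs(log2fc) >= 1,
    ifelse(log2fc > 0, "up", "down"), "ns"
  )
  data.frame(
    feature_id = rownames(counts),
    log2fc = log2fc,
    mean_log2cpm = mean_log2cpm,
    p_raw = p_raw,
    fdr = fdr,
    direction = direction,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Select a differential expression signature
#'
#' Features passing both an FDR cap and a minimum absolute log2 fold change,
#' ranked by raw p-value ascending (ties broken by larger |log2fc|, then
#' lexicographic feature id) and optionally truncated to the top n.
#'
#' @param de_table A DE table from [nb_lrt()].
#' @param fdr_max Maximum BH-adjusted p.
#' @param min_abs_log2fc Minimum |log2fc|.
#' @param top_n Optional truncation; a warning is raised if fewer features
#'   pass than requested.
#' @return Character vector of feature ids, ranked.
#' @export
select_signature <- function(de_table, fdr_max = 0.05, min_abs_log2fc = 1,
                             top_n = NULL) {
  if (fdr_max <= 0 || min_abs_log2fc < 0) stop("invalid thresholds")
  pass <- de_table[de_table$fdr <= fdr_max &
    abs(de_table$log2fc) >= min_abs_log2fc, , drop = FALSE]
  if (nrow(pass) == 0) {
    warning("no features pass the signature thresholds")
    return(character(0))
  }
  ord <- order(pass$p_raw, -abs(pass$log2fc), pass$feature_id)
  ids <- pass$feature_id[ord]
  if (!is.null(top_n)) {
    if (length(ids) < top_n) {
      warning(sprintf(
        "only %d features pass thresholds (top_n = %d requested)",
        length(ids), top_n
      ))
    }
    ids <- utils::head(ids, top_n)
  }
  ids
}

#' Categorise features for a volcano plot
#'
#' Two-tier significance labels: `"dark"` for FDR <= `fdr_max` and
#' |log2fc| >= `min_abs_log2fc`; `"light"` for raw p <= `p_max` and
#' |log2fc| >= `min_abs_log2fc` but not dark; `"ns"` otherwise.
#'
#' @param de_table A DE table from [nb_lrt()].
#' @param fdr_max,p_max,min_abs_log2fc Thresholds.
#' @return The DE table with an added `volcano_category` column.
#' @export
volcano_categories <- function(de_table, fdr_max = 0.05, p_max = 0.05,
                               min_abs_log2fc = 1) {
  dark <- de_table$fdr <= fdr_max & abs(de_table$log2fc) >= min_abs_log2fc
  light <- !dark & de_table$p_raw <= p_max &
    abs(de_table$log2fc) >= min_abs_log2fc
  de_table$volcano_category <- ifelse(dark, "dark", ifelse(light, "light", "ns"))
  de_table
}
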