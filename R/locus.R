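#' Define a genomic locus
#'
#' Coordinates are 1-based inclusive throughout the package (BED input is
#' converted at the boundary).
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param name Optional label.
#' @return A list of class `locus_definition`.
#' @export
locus_definition <- function(chrom, start, end, name = NULL) {
  if (start > end) stop("locus start must be <= end")
  structure(
    list(chrom = chrom, start = start, end = end, name = name),
    class = "locus_definition"
  )
}

#' @export
format.locus_definition <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom, format(x$start, scientific = FALSE),
    format(x$end, scientific = FALSE))
}

#' @export
print.locus_definition <- function(x, ...) {
  cat(sprintf(
    "locus %s%s\n", format(x),
    if (is.null(x$name)) "" else paste0(" (", x$name, ")")
  ))
  invisible(x)
}

#' Parse a locus string such as "chr14:100,825,000-101,070,000"
#'
#' @param x A `"chrom:start-end"` string; thousands separators are allowed.
#' @param name Optional label.
#' @return A [locus_definition()].
#' @export
parse_locus <- function(x, name = NULL) {
  x <- gsub(",", "", x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse locus string: ", x)
  locus_definition(m[2], as.numeric(m[3]), as.numeric(m[4]), name = name)
}

#' Assign features to a locus by midpoint
#'
#' A feature is a member iff it lies on the locus chromosome and its
#' midpoint falls inside the interval (boundaries inclusive). Features
#' without coordinates are excluded with a warning.
#'
#' @param annotation Data frame with columns `feature_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param locus A [locus_definition()].
#' @return Character vector of member feature ids, in genomic order.
#' @export
assign_locus_membership <- function(annotation, locus) {
  need <- c("feature_id", "chrom", "start", "end")
  if (!all(need %in% names(annotation))) {
    stop("annotation must have columns ", paste(need, collapse = ", "))
  }
  ok <- !is.na(annotation$chrom) & annotation$chrom != "" &
    is.finite(annotation$start) & is.finite(annotation$end)
  if (any(!ok)) {
    warning(sum(!ok), " features lack coordinates and were excluded")
    annotation <- annotation[ok, , drop = FALSE]
  }
  mid <- (annotation$start + annotation$end) / 2
  member <- annotation$chrom == locus$chrom &
    mid >= locus$start & mid <= locus$end
  members <- annotation[member, , drop = FALSE]
  members$feature_id[order(members$start)]
}

#' Locus-wide expression summary by group
#'
#' Per-sample mean log2-CPM over the member features, per-group means, all
#' pairwise two-group Wilcoxon rank-sum tests (exact when feasible), and a
#' per-member direction tally: for each group pair, the fraction of members
#' whose group-mean expression is lower in the second group.
#'
#' @param log2cpm Numeric matrix (features x samples).
#' @param members Character vector of member feature ids (must be rows of
#'   `log2cpm`).
#' @param groups Factor (or coercible) of group labels per sample.
#' @return A list of class `locus_summary`: `sample_means`, `group_means`,
#'   `tests` (data frame: group_a, group_b, statistic, p_value, method),
#'   `member_direction` (data frame: group_a, group_b,
#'   frac_members_lower_in_b).
#' @export
locus_group_summary <- function(log2cpm, members, groups) {
  members <- intersect(members, rownames(log2cpm))
  if (length(members) == 0) stop("no member features present in the matrix")
  groups <- as.factor(groups)
  if (length(groups) != ncol(log2cpm)) stop("groups must match samples")
  sub <- log2cpm[members, , drop = FALSE]
  sample_means <- colMeans(sub)
  group_means <- tapply(sample_means, groups, mean)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  tests <- data.frame()
  direction <- data.frame()
  for (j in seq_len(ncol(pairs))) {
    ga <- pairs[1, j]
    gb <- pairs[2, j]
    tr <- wilcoxon_rank_sum(
      sample_means[groups == ga], sample_means[groups == gb]
    )
    tests <- rbind(tests, data.frame(
      group_a = ga, group_b = gb,
      statistic = tr$statistic, p_value = tr$p_value, method = tr$method,
      stringsAsFactors = FALSE
    ))
    mean_a <- rowMeans(sub[, groups == ga, drop = FALSE])
    mean_b <- rowMeans(sub[, groups == gb, drop = FALSE])
    direction <- rbind(direction, data.frame(
      group_a = ga, group_b = gb,
      frac_members_lower_in_b = mean(mean_b < mean_a),
      stringsAsFactors = FALSE
    ))
  }
  structure(
    list(
      sample_means = sample_means, group_means = group_means,
      tests = tests, member_direction = direction, members = members
    ),
    class = "locus_summary"
  )
}

#' @export
print.locus_summary <- function(x, ...) {
  cat(sprintf("locus_summary: %d members\n", length(x$members)))
  cat("group means (log2-CPM):\n")
  print(round(x$group_means, 3))
  invisible(x)
}

#' Per-member ribbon summary (median and IQR per group)
#'
#' Linear-interpolation (type-7) quantiles; rows ordered by genomic start.
#'
#' @param log2cpm Numeric matrix (features x samples).
#' @param annotation Annotation data frame (for genomic order).
#' @param members Member feature ids.
#' @param groups Factor of group labels per sample.
#' @return Data frame: `feature_id`, `genomic_index`, `group`, `median`,
#'   `q25`, `q75`.
#' @export
ribbon_summary <- function(log2cpm, annotation, members, groups) {
  groups <- as.factor(groups)
  ann <- annotation[match(members, annotation$feature_id), , drop = FALSE]
  ord <- order(ann$start)
  members <- members[ord]
  out <- list()
  for (i in seq_along(members)) {
    v <- log2cpm[members[i], ]
    for (g in levels(groups)) {
      vg <- v[groups == g]
      q <- quantile(vg, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1]] <- data.frame(
        feature_id = members[i], genomic_index = i, group = g,
        median = q[2], q25 = q[1], q75 = q[3], stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' All-pairs co-expression across a locus and its flanks
#'
#' Selects every annotated feature whose midpoint lies within `window` bp of
#' the locus boundaries (locus members included), orders them genomically,
#' and returns the all-pairs Pearson correlation matrix with BH-adjusted
#' p-values. Degenerate (zero-variance) features are retained with `NA`
#' entries and flagged.
#'
#' @param log2cpm Numeric matrix (features x samples); may mix mRNA and
#'   miRNA rows.
#' @param annotation Annotation data frame.
#' @param locus A [locus_definition()].
#' @param window Flanking window in bp on each side.
#' @return List: `r` (correlation matrix in genomic order, unit diagonal),
#'   `p_adj` (BH over the upper triangle), `feature_id`, `is_member`,
#'   `degenerate`.
#' @export
coexpression_matrix <- function(log2cpm, annotation, locus, window = 5e5) {
  wide <- locus_definition(
    locus$chrom, max(1, locus$start - window), locus$end + window
  )
  selected <- assign_locus_membership(annotation, wide)
  selected <- selected[selected %in% rownames(log2cpm)]
  if (length(selected) < 2) stop("fewer than 2 features in the window")
  members <- assign_locus_membership(annotation, locus)
  sub <- log2cpm[selected, , drop = FALSE]
  k <- nrow(sub)
  degenerate <- apply(sub, 1, sd) == 0
  r <- matrix(NA_real_, k, k, dimnames = list(selected, selected))
  p <- matrix(NA_real_, k, k, dimnames = list(selected, selected))
  ok <- !degenerate
  if (any(ok)) {
    r[ok, ok] <- cor(t(sub[ok, , drop = FALSE]))
    n <- ncol(sub)
    rr <- r[ok, ok, drop = FALSE]
    rr2 <- pmin(1 - 1e-15, rr^2)
    tt <- abs(rr) * sqrt((n - 2) / (1 - rr2))
    p[ok, ok] <- 2 * pt(-tt, df = n - 2)
  }
  diag(r)[!degenerate] <- 1
  ut <- upper.tri(p)
  vals <- p[ut]
  adj <- rep(NA_real_, length(vals))
  adj[!is.na(vals)] <- bh_adjust(vals[!is.na(vals)])
  p_adj <- matrix(NA_real_, k, k, dimnames = dimnames(p))
  p_adj[ut] <- adj
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate features flagged (zero variance)")
  }
  list(
    r = r, p_adj = p_adj, feature_id = selected,
    is_member = selected %in% members, degenerate = degenerate
  )
}

#' Correlate the locus-mean profile with a single gene
#'
#' @param locus_means Per-sample mean log2-CPM over locus members (e.g. the
#'   `sample_means` of [locus_group_summary()]).
#' @param gene_log2cpm Log2-CPM vector of one gene, aligned by sample.
#' @return A `test_result` from [pearson_corr()].
#' @export
locus_vs_gene_correlation <- function(locus_means, gene_log2cpm) {
  if (!is.null(names(locus_means)) && !is.null(names(gene_log2cpm))) {
    if (!setequal(names(locus_means), names(gene_log2cpm))) {
      stop("sample names do not match")
    }
    gene_log2cpm <- gene_log2cpm[names(locus_means)]
  }
  pearson_corr(locus_means, gene_log2cpm)
}

#' Cluster samples by locus expression profiles
#'
#' Member profiles are z-scored per miRNA (so highly expressed members do not
#' dominate the Euclidean metric), samples are clustered with
#' [kmeans_pp()], and clusters are labelled `high` / `intermediate` / `low`
#' (for k = 3; `cluster1..k` otherwise) by descending mean un-scaled
#' expression.
#'
#' @param log2cpm Numeric matrix (features x samples).
#' @param members Member feature ids.
#' @param groups Factor of subgroup labels per sample (for the contingency
#'   table).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param fisher Also run Fisher's exact test on the subgroup x cluster
#'   table (off by default: the contingency counts are the primary report).
#' @return List: `assignment` (factor per sample), `contingency`
#'   (subgroup x cluster table), `kmeans` (raw [kmeans_pp()] fit), and
#'   `fisher_p` when requested.
#' @export
cluster_samples <- function(log2cpm, members, groups, k = 3, seed = 1,
                            fisher = FALSE) {
  members <- intersect(members, rownames(log2cpm))
  if (length(members) == 0) stop("no member features present")
  groups <- as.factor(groups)
  sub <- log2cpm[members, , drop = FALSE]
  keep <- apply(sub, 1, sd) > 0
  z <- t(scale(t(sub[keep, , drop = FALSE])))
  fit <- kmeans_pp(t(z), k = k, seed = seed)
  # label clusters by descending mean of the un-scaled locus expression
  locus_mean <- colMeans(sub)
  cl_mean <- tapply(locus_mean, fit$assignment, mean)
  ord <- order(cl_mean, decreasing = TRUE)
  labels <- if (k == 3) {
    c("high", "intermediate", "low")
  } else {
    paste0("cluster", seq_len(k))
  }
  lab_map <- character(k)
  lab_map[as.integer(names(cl_mean))[ord]] <- labels[seq_along(ord)]
  assignment <- factor(lab_map[fit$assignment], levels = labels)
  names(assignment) <- colnames(log2cpm)
  contingency <- table(group = groups, cluster = assignment)
  out <- list(
    assignment = assignment,
    contingency = contingency,
    kmeans = fit
  )
  if (fisher) {
    out$fisher_p <- stats::fisher.test(contingency,
      simulate.p.value = TRUE, B = 10000
    )$p.value
  }
  out
}
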