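#' Filter features with insufficient counts
#'
#' Keeps features with raw CPM (library-size normalised only) at or above
#' `min_cpm` in at least `min_samples` samples; both boundaries are
#' inclusive. The report partitions removed features into "not detectable"
#' (zero in every sample) and "low count" (non-zero but failing the rule),
#' mirroring the three-way partition conventionally reported for miRNA-seq.
#'
#' @param m A `count_matrix` (or bare counts matrix).
#' @param min_cpm Minimum CPM (must be > 0).
#' @param min_samples Minimum number of samples meeting `min_cpm`.
#' @return List with `counts` (filtered `count_matrix`) and `report`
#'   (`n_total`, `n_undetectable`, `n_low`, `n_retained`).
#' @export
filter_low_counts <- function(m, min_cpm = 1, min_samples) {
  m <- as_count_matrix(m)
  if (min_cpm <= 0) stop("min_cpm must be positive")
  if (min_samples > ncol(m$counts)) {
    stop("min_samples exceeds the number of samples")
  }
  lib <- colSums(m$counts)
  if (any(lib == 0)) stop("sample with zero total counts")
  cpm0 <- t(t(m$counts) / lib) * 1e6
  keep <- rowSums(cpm0 >= min_cpm) >= min_samples
  undetectable <- rowSums(m$counts) == 0
  if (!any(keep)) {
    stop("no features pass filtering; lower min_cpm or min_samples")
  }
  report <- list(
    n_total = nrow(m$counts),
    n_undetectable = sum(undetectable),
    n_low = sum(!keep & !undetectable),
    n_retained = sum(keep)
  )
  list(counts = m[keep, ], report = report)
}

#' Counts per million, optionally log2 with a prior count
#'
#' `cpm = count / effective_size * 1e6`; the log2 form is
#' `log2((count + prior) / (effective_size + 2 * prior) * 1e6)`.
#' Effective sizes come from `norm` when supplied (library size x TMM
#' factor), otherwise raw column totals are used.
#'
#' @param m A `count_matrix` or bare counts matrix.
#' @param norm Optional `normalization_state`.
#' @param log2 Return log2-CPM?
#' @param prior Prior count added in the log2 form (must be > 0).
#' @return Numeric matrix, same dimensions and dimnames as the counts.
#' @export
cpm <- function(m, norm = NULL, log2 = FALSE, prior = 0.5) {
  m <- as_count_matrix(m)
  eff <- if (is.null(norm)) colSums(m$counts) else norm$effective_sizes[colnames(m$counts)]
  if (any(is.na(eff)) || any(eff <= 0)) stop("invalid or zero library size")
  if (log2) {
    if (prior <= 0) stop("prior must be positive for log2-CPM")
    base::log2(t(t(m$counts + prior) / (eff + 2 * prior)) * 1e6)
  } else {
    t(t(m$counts) / eff) * 1e6
  }
}

# Upper-quartile of non-zero-adjusted CPM, used only to pick the TMM
# reference sample.
tmm_ref_quantile <- function(counts, lib, p = 0.75) {
  apply(counts, 2, function(y) quantile(y, p = p)) / lib
}

tmm_pair_factor <- function(y, lib, yr, libr,
                            logratio_trim = 0.3, sum_trim = 0.05) {
  keep0 <- y > 0 & yr > 0
  y <- y[keep0]
  yr <- yr[keep0]
  if (length(y) == 0) {
    warning("no co-expressed features with the reference; factor set to 1")
    return(1)
  }
  m_val <- log2((y / lib) / (yr / libr))
  a_val <- 0.5 * log2((y / lib) * (yr / libr))
  v <- (lib - y) / (lib * y) + (libr - yr) / (libr * yr)
  if (max(abs(m_val)) < 1e-6) return(1)
  n <- length(m_val)
  lo_l <- floor(n * logratio_trim) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * sum_trim) + 1
  hi_s <- n + 1 - lo_s
  rm_ <- rank(m_val)
  ra_ <- rank(a_val)
  keep <- rm_ >= lo_l & rm_ <= hi_l & ra_ >= lo_s & ra_ <= hi_s
  if (!any(keep)) return(1)
  2^(sum(m_val[keep] / v[keep]) / sum(1 / v[keep]))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: each sample is compared with a reference sample
#' (the one whose 75th CPM percentile is closest to the mean), log ratios are
#' doubly trimmed (30% on M, 5% on A), and the trimmed mean is weighted by
#' the inverse asymptotic (delta-method) variance of each log ratio. Factors
#' are renormalized to geometric mean 1.
#'
#' @param m A `count_matrix` or bare counts matrix with >= 2 samples.
#' @return A `normalization_state`.
#' @export
tmm_factors <- function(m) {
  m <- as_count_matrix(m)
  counts <- m$counts
  if (ncol(counts) < 2) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero total counts")
  uq <- tmm_ref_quantile(counts, lib)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    tmm_pair_factor(counts[, s], lib[s], counts[, ref], lib[ref])
  }, numeric(1))
  names(f) <- colnames(counts)
  normalization_state(lib, f)
}
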