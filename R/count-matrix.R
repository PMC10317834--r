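#' Construct a count matrix
#'
#' Lightweight container for a feature-by-sample matrix of sequencing read
#' counts, the substrate of every downstream stage. Counts must be
#' non-negative integers and feature/sample identifiers must be unique.
#'
#' @param counts Numeric matrix (features x samples) of non-negative integer
#'   counts with rownames (feature ids) and colnames (sample ids).
#' @param feature_type Either `"mRNA"` or `"miRNA"`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer storage matrix) and `feature_type`.
#' @examples
#' m <- count_matrix(matrix(0:3, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' dim(m)
#' @export
count_matrix <- function(counts, feature_type = c("mRNA", "miRNA")) {
  feature_type <- match.arg(feature_type)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry feature (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop("duplicate feature id: ", dup)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1L]
    stop("duplicate sample id: ", dup)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-integer count at feature '%s', sample '%s'",
      rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]
    ))
  }
  storage.mode(counts) <- "double" # keep double: big libraries overflow int
  structure(
    list(counts = counts, feature_type = feature_type),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d %s features x %d samples (total %.3g reads)\n",
    nrow(x$counts), x$feature_type, ncol(x$counts), sum(x$counts)
  ))
  invisible(x)
}

#' Subset a count matrix
#'
#' @param x A `count_matrix`.
#' @param i,j Row (feature) and column (sample) indices.
#' @param ... Unused.
#' @return A `count_matrix` restricted to the selected features/samples.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  cm <- x$counts
  if (missing(i)) i <- seq_len(nrow(cm))
  if (missing(j)) j <- seq_len(ncol(cm))
  count_matrix(cm[i, j, drop = FALSE], feature_type = x$feature_type)
}

# Accept either a count_matrix or a bare matrix everywhere downstream.
as_count_matrix <- function(x, feature_type = "mRNA") {
  if (inherits(x, "count_matrix")) x else count_matrix(x, feature_type)
}

#' Normalization state for a count matrix
#'
#' Bundles per-sample library sizes with TMM scaling factors. The factors are
#' renormalized so that their geometric mean is 1; the effective size of a
#' sample is `library_size * tmm_factor`.
#'
#' @param library_sizes Named numeric vector of per-sample read totals.
#' @param tmm_factors Named numeric vector of positive scaling factors
#'   (default: all 1).
#' @return An object of class `normalization_state` with elements
#'   `library_sizes`, `tmm_factors` and `effective_sizes`.
#' @export
normalization_state <- function(library_sizes,
                                tmm_factors = rep(1, length(library_sizes))) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (any(tmm_factors <= 0)) stop("TMM factors must be positive")
  tmm_factors <- tmm_factors / exp(mean(log(tmm_factors)))
  names(tmm_factors) <- names(library_sizes)
  structure(
    list(
      library_sizes = library_sizes,
      tmm_factors = tmm_factors,
      effective_sizes = library_sizes * tmm_factors
    ),
    class = "normalization_state"
  )
}

#' @export
print.normalization_state <- function(x, ...) {
  cat(sprintf(
    "normalization_state: %d samples, TMM factors in [%.3f, %.3f]\n",
    length(x$library_sizes), min(x$tmm_factors), max(x$tmm_factors)
  ))
  invisible(x)
}
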