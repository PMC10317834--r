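# File-format boundary. Counts travel as TSV (feature ids in the first
# column, header row of sample ids) or MatrixMarket with .features.tsv /
# .samples.tsv sidecars; annotation as 6-column BED (0-based half-open,
# converted here to the internal 1-based inclusive convention).

mtx_sidecars <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  c(features = paste0(stem, ".features.tsv"), samples = paste0(stem, ".samples.tsv"))
}

#' Read a count matrix from TSV or MatrixMarket
#'
#' @param path File path (`.tsv` or `.mtx`; format inferred from the
#'   extension unless given).
#' @param format `"auto"`, `"tsv"` or `"mtx"`.
#' @param feature_type `"mRNA"` or `"miRNA"`.
#' @return A [count_matrix()]; non-integer entries and duplicate ids are
#'   rejected with informative errors.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx"),
                        feature_type = "mRNA") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- df[[1]]
    if (anyDuplicated(ids)) {
      stop("duplicate feature id: ", ids[duplicated(ids)][1])
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    return(count_matrix(m, feature_type))
  }
  side <- mtx_sidecars(path)
  if (!all(file.exists(side))) {
    stop("MatrixMarket sidecar files missing: ", paste(side, collapse = ", "))
  }
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(side["features"])
  colnames(m) <- readLines(side["samples"])
  count_matrix(m, feature_type)
}

#' Write a count matrix to TSV or MatrixMarket
#'
#' @param m A `count_matrix`.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"` (sidecar id files written alongside).
#' @return Invisibly, `path`.
#' @export
write_counts <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  m <- as_count_matrix(m)
  if (format == "tsv") {
    df <- data.frame(
      feature_id = rownames(m$counts), m$counts,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE), path)
    side <- mtx_sidecars(path)
    writeLines(rownames(m$counts), side["features"])
    writeLines(colnames(m$counts), side["samples"])
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("metadata needs columns sample_id and group")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df
}

#' Read a 6-column BED annotation
#'
#' BED is 0-based half-open; intervals are converted to the internal 1-based
#' inclusive convention (`start + 1`, `end` unchanged). Comment, `track` and
#' `browser` lines are skipped. Strand is retained (it is not used for locus
#' membership).
#'
#' @param path BED file path.
#' @return Annotation data frame: `feature_id`, `chrom`, `start`, `end`,
#'   `strand` (no feature type; recover it by matching ids against the count
#'   matrices).
#' @export
read_bed_annotation <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) stop("no records in BED file")
  parts <- strsplit(lines, "\t")
  ncols <- lengths(parts)
  if (any(ncols < 6)) {
    stop("BED line ", which(ncols < 6)[1], " has fewer than 6 columns")
  }
  chrom <- vapply(parts, `[[`, character(1), 1)
  start0 <- as.numeric(vapply(parts, `[[`, character(1), 2))
  end0 <- as.numeric(vapply(parts, `[[`, character(1), 3))
  name <- vapply(parts, `[[`, character(1), 4)
  strand <- vapply(parts, `[[`, character(1), 6)
  bad <- which(!is.finite(start0) | !is.finite(end0) | start0 >= end0)
  if (length(bad) > 0) {
    stop("invalid interval at BED line ", bad[1])
  }
  if (!all(strand %in% c("+", "-", "."))) {
    stop("invalid strand field (expected +, - or .)")
  }
  data.frame(
    feature_id = name, chrom = chrom,
    start = start0 + 1, end = end0, strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Write an annotation table as 6-column BED
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention on write.
#'
#' @param annotation Annotation data frame (`feature_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_annotation <- function(annotation, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t0\t%s",
    annotation$chrom, as.integer(annotation$start - 1),
    as.integer(annotation$end), annotation$feature_id, annotation$strand
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a target database from TSV
#'
#' @param path TSV with columns `mirna_id`, `gene_id`, `source` and
#'   optionally `score`.
#' @return A [target_database()].
#' @export
read_target_database <- function(path) {
  target_database(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a target database to TSV
#'
#' @param db A `target_database`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_target_database <- function(db, path) {
  utils::write.table(as.data.frame(db), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
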