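#' Construct a target-interaction database
#'
#' A set of directed (miRNA -> gene) putative interactions with a source
#' label and an optional score in `[0, 100]`. Duplicate
#' (miRNA, gene, source) triples are collapsed.
#'
#' @param entries Data frame with columns `mirna_id`, `gene_id`, `source`
#'   and optionally `score`.
#' @return A data frame of class `target_database`.
#' @export
target_database <- function(entries) {
  need <- c("mirna_id", "gene_id", "source")
  if (!all(need %in% names(entries))) {
    stop("database needs columns ", paste(need, collapse = ", "))
  }
  if (!"score" %in% names(entries)) {
    entries$score <- rep(NA_real_, nrow(entries))
  }
  entries <- entries[, c("mirna_id", "gene_id", "source", "score")]
  if (nrow(entries) > 0) {
    if (any(!nzchar(entries$mirna_id)) || any(!nzchar(entries$gene_id))) {
      stop("empty feature ids in database")
    }
    if (any(!is.na(entries$score) &
      (entries$score < 0 | entries$score > 100))) {
      stop("scores must lie in [0, 100]")
    }
    key <- paste(entries$mirna_id, entries$gene_id, entries$source, sep = "\r")
    entries <- entries[!duplicated(key), , drop = FALSE]
    rownames(entries) <- NULL
  }
  class(entries) <- c("target_database", "data.frame")
  entries
}

# Distinct (miRNA, gene) pairs over the union of databases, case-folded
# keys, no source aggregation: the fast path for interaction counting.
db_distinct_pairs <- function(dbs) {
  if (inherits(dbs, "target_database")) dbs <- list(dbs)
  if (length(dbs) == 0) stop("empty database list")
  mirna <- unlist(lapply(dbs, function(d) d$mirna_id), use.names = FALSE)
  gene <- unlist(lapply(dbs, function(d) d$gene_id), use.names = FALSE)
  key <- paste(tolower(mirna), tolower(gene), sep = "\r")
  keep <- !duplicated(key)
  list(mirna_id = mirna[keep], gene_id = gene[keep])
}

# Distinct (miRNA, gene) pairs over the union of one or more databases,
# with ids case-folded for matching. Returns a data.frame with lower-cased
# keys plus original ids, supporting sources and best score per pair.
db_union_pairs <- function(dbs) {
  if (inherits(dbs, "target_database")) dbs <- list(dbs)
  if (length(dbs) == 0) stop("empty database list")
  all <- do.call(rbind, lapply(dbs, function(d) as.data.frame(d)))
  if (nrow(all) == 0) {
    return(data.frame(
      key = character(0), mirna_id = character(0), gene_id = character(0),
      sources = character(0), n_sources = integer(0), best_score = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  key <- paste(tolower(all$mirna_id), tolower(all$gene_id), sep = "\r")
  sources <- vapply(
    split(all$source, key),
    function(s) paste(sort(unique(s)), collapse = ","), character(1)
  )
  n_sources <- vapply(
    split(all$source, key),
    function(s) length(unique(s)), integer(1)
  )
  best <- vapply(split(all$score, key), function(s) {
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
  }, numeric(1))
  first <- !duplicated(key)
  ord <- key[first]
  data.frame(
    key = ord,
    mirna_id = all$mirna_id[first],
    gene_id = all$gene_id[first],
    sources = unname(sources[ord]),
    n_sources = unname(n_sources[ord]),
    best_score = unname(best[ord]),
    stringsAsFactors = FALSE
  )
}

#' All-pairs miRNA x mRNA correlation
#'
#' One record per (miRNA, mRNA) pair: Pearson r on the supplied expression
#' matrices (conventionally log2-CPM), two-sided p from the t transform, and
#' BH adjustment across all tested pairs jointly. Degenerate (zero-variance)
#' features are skipped with a warning.
#'
#' @param mirna_log2cpm,mrna_log2cpm Numeric matrices (features x samples)
#'   sharing the same sample columns (order may differ).
#' @return Data frame: `mirna_id`, `gene_id`, `r`, `p_raw`, `p_adj`.
#' @export
correlate_pairs <- function(mirna_log2cpm, mrna_log2cpm) {
  if (!setequal(colnames(mirna_log2cpm), colnames(mrna_log2cpm))) {
    miss <- c(
      setdiff(colnames(mirna_log2cpm), colnames(mrna_log2cpm)),
      setdiff(colnames(mrna_log2cpm), colnames(mirna_log2cpm))
    )
    stop("sample mismatch: ", paste(miss, collapse = ", "))
  }
  mrna_log2cpm <- mrna_log2cpm[, colnames(mirna_log2cpm), drop = FALSE]
  n <- ncol(mirna_log2cpm)
  if (n < 3) stop("need at least 3 shared samples")
  deg_mi <- apply(mirna_log2cpm, 1, sd) == 0
  deg_mr <- apply(mrna_log2cpm, 1, sd) == 0
  if (any(deg_mi) || any(deg_mr)) {
    warning(sum(deg_mi) + sum(deg_mr), " degenerate features skipped")
  }
  mi <- mirna_log2cpm[!deg_mi, , drop = FALSE]
  mr <- mrna_log2cpm[!deg_mr, , drop = FALSE]
  r <- cor(t(mi), t(mr))
  r2 <- pmin(1 - 1e-15, r^2)
  tt <- abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(-tt, df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  out <- data.frame(
    mirna_id = rep(rownames(mi), times = ncol(r)),
    gene_id = rep(colnames(r), each = nrow(r)),
    r = as.vector(r),
    p_raw = as.vector(p),
    stringsAsFactors = FALSE
  )
  out$p_adj <- bh_adjust(out$p_raw)
  out
}

#' Keep significant, negatively correlated pairs
#'
#' @param pairs Data frame from [correlate_pairs()].
#' @param p_adj_max Inclusive threshold on the BH-adjusted p.
#' @return The filtered data frame (`r < 0` and `p_adj <= p_adj_max`).
#' @export
filter_negative_significant <- function(pairs, p_adj_max = 0.05) {
  if (p_adj_max <= 0 || p_adj_max > 1) stop("p_adj_max must lie in (0, 1]")
  pairs[pairs$r < 0 & pairs$p_adj <= p_adj_max, , drop = FALSE]
}

#' Intersect correlation pairs with target databases
#'
#' Keeps pairs present in at least `min_sources` distinct database sources
#' (exact string match after case-folding; no alias resolution) and attaches
#' the supporting source labels and best score.
#'
#' @param pairs Data frame with `mirna_id`, `gene_id` columns.
#' @param dbs A `target_database` or list of them.
#' @param min_sources Minimum number of distinct supporting sources.
#' @return The annotated subset of `pairs` with added `sources`,
#'   `n_sources`, `best_score` columns.
#' @export
intersect_with_databases <- function(pairs, dbs, min_sources = 1) {
  if (min_sources < 1) stop("min_sources must be >= 1")
  u <- db_union_pairs(dbs)
  key <- paste(tolower(pairs$mirna_id), tolower(pairs$gene_id), sep = "\r")
  idx <- match(key, u$key)
  hit <- !is.na(idx) & u$n_sources[idx] >= min_sources
  out <- pairs[hit, , drop = FALSE]
  out$sources <- u$sources[idx[hit]]
  out$n_sources <- u$n_sources[idx[hit]]
  out$best_score <- u$best_score[idx[hit]]
  rownames(out) <- NULL
  out
}

#' Build the bipartite miRNA:mRNA interaction network
#'
#' Edges are the database-supported, negatively correlated pairs; edge
#' weight is |r|, and nodes carry their feature type and (when DE tables are
#' supplied) log2 fold change as a fill attribute. Duplicate pairs are
#' collapsed to one edge.
#'
#' @param pairs Annotated pairs from [intersect_with_databases()] (columns
#'   `mirna_id`, `gene_id`, `r`, `p_adj`, `sources`).
#' @param de_mirna,de_mrna Optional DE tables from [nb_lrt()], used to
#'   attach `log2fc` node attributes (missing features get `NA` with a
#'   warning).
#' @return An `igraph` bipartite graph; miRNA vertices have `type = TRUE`.
#' @export
build_network <- function(pairs, de_mirna = NULL, de_mrna = NULL) {
  pairs <- pairs[!duplicated(pairs[, c("mirna_id", "gene_id")]), , drop = FALSE]
  mirnas <- unique(pairs$mirna_id)
  genes <- unique(pairs$gene_id)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(mirnas),
    name = mirnas, feature_type = "miRNA", type = TRUE
  )
  g <- igraph::add_vertices(g, length(genes),
    name = genes, feature_type = "mRNA", type = FALSE
  )
  if (nrow(pairs) > 0) {
    edges <- as.vector(rbind(pairs$mirna_id, pairs$gene_id))
    g <- igraph::add_edges(g, edges,
      r = pairs$r, p_adj = pairs$p_adj,
      weight = abs(pairs$r),
      sources = if ("sources" %in% names(pairs)) pairs$sources else NA
    )
  }
  lfc <- rep(NA_real_, igraph::vcount(g))
  lookup <- function(tab, ids) tab$log2fc[match(ids, tab$feature_id)]
  vn <- igraph::V(g)$name
  is_mi <- igraph::V(g)$type
  if (!is.null(de_mirna)) lfc[is_mi] <- lookup(de_mirna, vn[is_mi])
  if (!is.null(de_mrna)) lfc[!is_mi] <- lookup(de_mrna, vn[!is_mi])
  if ((!is.null(de_mirna) || !is.null(de_mrna)) && anyNA(lfc)) {
    warning("log2fc undefined for ", sum(is.na(lfc)), " nodes")
  }
  igraph::V(g)$log2fc <- lfc
  g
}

#' Ranked per-node degree tables
#'
#' @param net Network from [build_network()].
#' @return List of two data frames (`mirna`, `mrna`) with `feature_id` and
#'   `degree`, ranked by descending degree, ties broken lexicographically.
#' @export
degree_summary <- function(net) {
  side <- function(keep) {
    ids <- igraph::V(net)$name[keep]
    deg <- igraph::degree(net)[keep]
    out <- data.frame(
      feature_id = ids, degree = unname(deg),
      stringsAsFactors = FALSE
    )
    out[order(-out$degree, out$feature_id), , drop = FALSE]
  }
  list(
    mirna = side(igraph::V(net)$type),
    mrna = side(!igraph::V(net)$type)
  )
}

#' Fraction of a signature covered by network edges
#'
#' @param net Network from [build_network()].
#' @param signature Character vector of signature mRNA ids.
#' @return List with `covered` (count of signature mRNAs carrying >= 1
#'   edge) and `fraction` (`covered / length(signature)`).
#' @export
fraction_of_signature_targeted <- function(net, signature) {
  if (length(signature) == 0) stop("signature must be non-empty")
  deg <- igraph::degree(net)
  present <- intersect(signature, igraph::V(net)$name)
  covered <- sum(deg[present] >= 1)
  list(covered = covered, fraction = covered / length(signature))
}

#' Export a network to SIF, GraphML or edge TSV
#'
#' SIF lines are `mirna<TAB>targets<TAB>gene`; GraphML carries all node and
#' edge attributes (via igraph); the edge TSV holds the full records. All
#' formats round-trip through [import_network()].
#'
#' @param net Network from [build_network()].
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"edge-tsv"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    # GraphML writer rejects NA reals in attributes; encode as NaN
    if (!is.null(igraph::V(net)$log2fc)) {
      lfc <- igraph::V(net)$log2fc
      lfc[is.na(lfc)] <- NaN
      igraph::V(net)$log2fc <- lfc
    }
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(net)
  if (format == "sif") {
    lines <- if (nrow(el) > 0) {
      paste(el[, 1], "targets", el[, 2], sep = "\t")
    } else {
      character(0)
    }
    writeLines(lines, path)
    return(invisible(path))
  }
  df <- data.frame(
    mirna_id = el[, 1], gene_id = el[, 2],
    r = if (igraph::ecount(net)) igraph::E(net)$r else numeric(0),
    p_adj = if (igraph::ecount(net)) igraph::E(net)$p_adj else numeric(0),
    sources = if (igraph::ecount(net)) igraph::E(net)$sources else character(0),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return An `igraph` graph (for `edge-tsv`, rebuilt via
#'   [build_network()]).
#' @export
import_network <- function(path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  build_network(df)
}
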