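# End-to-end orchestration: filter -> normalize -> DE (mRNA and miRNA) ->
# PCA / volcano exports -> locus analytics -> pair correlation -> database
# intersection -> network build/export -> enrichment, with a run manifest.

#' Pipeline configuration
#'
#' Paths to inputs, the group contrast, and every stage threshold. Defaults
#' follow the package's standard analysis: FDR <= 0.05 with |log2FC| >= 1
#' for signatures, top 200 by p-value, pair significance at adjusted
#' p <= 0.05 in >= 1 database source, and a 50,000-draw resampling null.
#'
#' @param mrna_counts,mirna_counts,metadata,annotation Paths to the count
#'   matrices (TSV/MTX), sample metadata TSV and BED annotation.
#' @param databases Character vector of target-database TSV paths.
#' @param locus Locus string (`"chr:start-end"`) or a [locus_definition()].
#' @param out_dir Output directory.
#' @param contrast List with `ref` and `alt`: group labels collapsed into
#'   the two DE arms (e.g. `ref = c("M-CLL-S", "M-CLL-NS")`,
#'   `alt = "U-CLL-S"`); `log2fc` is alt vs ref.
#' @param fdr_max,min_abs_log2fc,top_n Signature thresholds.
#' @param pair_p_adj_max,min_sources Network edge thresholds.
#' @param min_cpm,min_samples Filter thresholds; `min_samples = NULL` uses
#'   the smallest group size.
#' @param network_mirnas `"locus"` (locus members vs the signature, the
#'   default) or `"dem"` (differentially expressed miRNAs).
#' @param locus_k Number of sample clusters for the locus k-means.
#' @param flank_window Flanking window (bp) for the co-expression matrix.
#' @param B,seed Resampling depth and master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mrna_counts, mirna_counts, metadata, annotation,
                            databases, locus, out_dir,
                            contrast = list(
                              ref = c("M-CLL-S", "M-CLL-NS"),
                              alt = "U-CLL-S"
                            ),
                            fdr_max = 0.05, min_abs_log2fc = 1, top_n = 200,
                            pair_p_adj_max = 0.05, min_sources = 1,
                            min_cpm = 1, min_samples = NULL,
                            network_mirnas = c("locus", "dem"),
                            locus_k = 3, flank_window = 5e5,
                            B = 50000, seed = 1) {
  if (fdr_max <= 0 || fdr_max > 1 || pair_p_adj_max <= 0 ||
    pair_p_adj_max > 1 || min_abs_log2fc < 0 || B < 1) {
    stop("thresholds out of range")
  }
  structure(list(
    mrna_counts = mrna_counts, mirna_counts = mirna_counts,
    metadata = metadata, annotation = annotation, databases = databases,
    locus = locus, out_dir = out_dir, contrast = contrast,
    fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc, top_n = top_n,
    pair_p_adj_max = pair_p_adj_max, min_sources = min_sources,
    min_cpm = min_cpm, min_samples = min_samples,
    network_mirnas = match.arg(network_mirnas),
    locus_k = locus_k, flank_window = flank_window, B = B, seed = seed
  ), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, halting with the stage name on failure,
#' and writes all outputs plus a YAML run manifest (config snapshot, package
#' version, seed, per-stage row counts, MD5 checksums of every written
#' file). Reruns with the same inputs and seed are bitwise-stable.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop("cfg must be a pipeline_config")
  stage <- "setup"
  on_fail <- function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      call. = FALSE
    )
  }
  tryCatch({
    stage <- "read-inputs"
    for (p in c(
      cfg$mrna_counts, cfg$mirna_counts, cfg$metadata,
      cfg$annotation, cfg$databases
    )) {
      if (!file.exists(p)) stop("input not readable: ", p)
    }
    mrna <- read_counts(cfg$mrna_counts, feature_type = "mRNA")
    mirna <- read_counts(cfg$mirna_counts, feature_type = "miRNA")
    meta <- read_metadata(cfg$metadata)
    ann <- read_bed_annotation(cfg$annotation)
    dbs <- lapply(cfg$databases, read_target_database)
    locus <- if (inherits(cfg$locus, "locus_definition")) {
      cfg$locus
    } else {
      parse_locus(cfg$locus)
    }

    stage <- "validate-config"
    labels <- unlist(cfg$contrast)
    if (!all(labels %in% meta$group)) {
      stop(
        "contrast labels absent from metadata: ",
        paste(setdiff(labels, meta$group), collapse = ", ")
      )
    }
    if (!setequal(meta$sample_id, colnames(mrna$counts)) ||
      !setequal(meta$sample_id, colnames(mirna$counts))) {
      stop("metadata samples do not match count matrices")
    }
    mrna <- mrna[, meta$sample_id]
    mirna <- mirna[, meta$sample_id]
    groups <- factor(meta$group)
    arm <- factor(
      ifelse(meta$group %in% cfg$contrast$alt, "alt", "ref"),
      levels = c("ref", "alt")
    )
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$out_dir, f)
    files <- character(0)
    counts <- list()

    stage <- "filter"
    min_samples <- if (is.null(cfg$min_samples)) {
      min(table(meta$group))
    } else {
      cfg$min_samples
    }
    fm <- filter_low_counts(mrna, cfg$min_cpm, min_samples)
    fi <- filter_low_counts(mirna, cfg$min_cpm, min_samples)
    counts$mrna_filter <- fm$report
    counts$mirna_filter <- fi$report

    stage <- "normalize"
    norm_m <- tmm_factors(fm$counts)
    norm_i <- tmm_factors(fi$counts)
    l2_m <- cpm(fm$counts, norm_m, log2 = TRUE)
    l2_i <- cpm(fi$counts, norm_i, log2 = TRUE)

    stage <- "differential-expression"
    de_m <- nb_lrt(fm$counts, arm, contrast = c("ref", "alt"), norm = norm_m)
    de_i <- nb_lrt(fi$counts, arm, contrast = c("ref", "alt"), norm = norm_i)
    files <- c(files, write_tsv(de_m, out("de_mrna.tsv")))
    files <- c(files, write_tsv(de_i, out("de_mirna.tsv")))
    files <- c(
      files,
      write_tsv(
        volcano_categories(de_m, cfg$fdr_max,
          min_abs_log2fc = cfg$min_abs_log2fc
        ),
        out("volcano_mrna.tsv")
      ),
      write_tsv(
        volcano_categories(de_i, cfg$fdr_max,
          min_abs_log2fc = cfg$min_abs_log2fc
        ),
        out("volcano_mirna.tsv")
      )
    )
    counts$n_deg <- sum(de_m$direction != "ns")
    counts$n_dem <- sum(de_i$direction != "ns")

    stage <- "pca"
    pc <- pca_svd(t(l2_m), n_components = min(5, ncol(l2_m) - 1))
    files <- c(files, write_tsv(
      data.frame(
        sample_id = rownames(pc$scores), group = meta$group,
        pc$scores
      ),
      out("pca_mrna_scores.tsv")
    ))

    stage <- "locus-analysis"
    members <- assign_locus_membership(ann, locus)
    members_mi <- intersect(members, rownames(l2_i))
    summ <- locus_group_summary(l2_i, members_mi, groups)
    files <- c(files, write_tsv(
      data.frame(
        sample_id = names(summ$sample_means),
        group = meta$group, mean_log2cpm = summ$sample_means
      ),
      out("locus_sample_means.tsv")
    ))
    files <- c(files, write_tsv(summ$tests, out("locus_tests.tsv")))
    files <- c(files, write_tsv(
      ribbon_summary(l2_i, ann, members_mi, groups),
      out("locus_ribbon.tsv")
    ))
    l2_all <- rbind(l2_i, l2_m)
    coex <- coexpression_matrix(l2_all, ann, locus, window = cfg$flank_window)
    files <- c(files, write_tsv(
      data.frame(feature_id = rownames(coex$r), round(coex$r, 6),
        check.names = FALSE
      ),
      out("locus_coexpression_r.tsv")
    ))
    cl <- cluster_samples(l2_i, members_mi, groups,
      k = cfg$locus_k,
      seed = cfg$seed
    )
    files <- c(files, write_tsv(
      as.data.frame(cl$contingency),
      out("locus_cluster_contingency.tsv")
    ))
    counts$n_locus_members <- length(members_mi)

    stage <- "signature"
    signature <- select_signature(
      de_m, cfg$fdr_max, cfg$min_abs_log2fc, cfg$top_n
    )
    if (length(signature) == 0) stop("empty mRNA signature")
    net_mirnas <- if (cfg$network_mirnas == "locus") {
      members_mi
    } else {
      de_i$feature_id[de_i$direction != "ns"]
    }
    if (length(net_mirnas) == 0) stop("no miRNAs selected for the network")
    counts$n_signature <- length(signature)

    stage <- "pair-correlation"
    pairs <- correlate_pairs(
      l2_i[net_mirnas, , drop = FALSE],
      l2_m[signature, , drop = FALSE]
    )
    neg <- filter_negative_significant(pairs, cfg$pair_p_adj_max)
    counts$n_pairs_tested <- nrow(pairs)
    counts$n_pairs_negative_significant <- nrow(neg)
    files <- c(files, write_tsv(neg, out("pairs_negative_significant.tsv")))

    stage <- "database-intersection"
    supported <- intersect_with_databases(neg, dbs, cfg$min_sources)
    counts$n_pairs_supported <- nrow(supported)

    stage <- "network"
    net <- build_network(supported, de_mirna = de_i, de_mrna = de_m)
    files <- c(files, export_network(net, out("network.sif"), "sif"))
    files <- c(files, export_network(net, out("network.graphml"), "graphml"))
    files <- c(files, export_network(net, out("network_edges.tsv"), "edge-tsv"))
    deg <- degree_summary(net)
    files <- c(files, write_tsv(deg$mirna, out("degree_mirna.tsv")))
    files <- c(files, write_tsv(deg$mrna, out("degree_mrna.tsv")))
    cov <- fraction_of_signature_targeted(net, signature)
    counts$n_network_edges <- igraph::ecount(net)
    counts$signature_covered <- cov$covered
    counts$signature_fraction <- cov$fraction

    stage <- "enrichment"
    enr <- run_enrichment(
      net_mirnas, signature, dbs,
      mirna_universe = rownames(l2_i), mrna_universe = rownames(l2_m),
      B = cfg$B, seed = cfg$seed
    )
    files <- c(files, out("enrichment_report.tsv"))
    write_enrichment_report(enr, out("enrichment_report.tsv"),
      histogram_path = out("enrichment_null_histogram.tsv"),
      seed = cfg$seed
    )
    files <- c(files, out("enrichment_null_histogram.tsv"))
    counts$enrichment_observed <- enr$observed_count
    counts$enrichment_null_mean <- enr$null_mean
    counts$enrichment_p_empirical <- enr$p_empirical

    stage <- "manifest"
    files <- unique(files)
    manifest <- list(
      package_version = as.character(utils::packageVersion("mirlink")),
      seed = cfg$seed,
      config = lapply(
        unclass(cfg)[setdiff(names(unclass(cfg)), "contrast")], identity
      ),
      contrast = cfg$contrast,
      stage_counts = counts,
      files = lapply(stats::setNames(files, basename(files)), function(f) {
        list(path = f, md5 = unname(tools::md5sum(f)))
      })
    )
    yaml::write_yaml(manifest, out("manifest.yaml"))
    invisible(manifest)
  }, error = on_fail)
}
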