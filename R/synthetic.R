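# Synthetic cohort generator. Emulates a three-subgroup bulk mRNA + miRNA
# sequencing study carrying a co-regulated genomic miRNA cluster with a
# stepwise subgroup gradient, a host lncRNA co-expressed with the cluster,
# planted differentially expressed mRNAs, and negatively coupled
# miRNA:mRNA regulatory pairs, plus a target database mixing true pairs
# with random decoys. Counts are NB2: var = mu + phi * mu^2, with
# log2 mu_fs = baseline_f + group effect + latent-factor loadings.

# Side-specific scalings of the pair latent variable: the repressed target
# responds 1:1 to the pair's regulatory activity on the log2 scale, while
# the measured miRNA reflects it with modest amplitude (so the locus
# gradient stays visible per member and targets keep detectable
# differential expression).
PAIR_LOADING_MIRNA <- 0.4
PAIR_LOADING_MRNA <- 1

#' Configuration for the synthetic cohort generator
#'
#' All defaults together define the emulated study conditions; see the
#' methods vignette for the rationale behind each value.
#'
#' @param n_per_group Samples per subgroup (3 subgroups).
#' @param n_mrna,n_mirna Numbers of expressed features.
#' @param lib_size_mrna,lib_size_mirna Expected assigned reads per sample.
#' @param dispersion NB dispersion phi (`var = mu + phi mu^2`); 0 gives
#'   Poisson counts.
#' @param baseline_log2_sd SD of the normal baseline log2 abundance spread.
#' @param cluster_size Number of co-regulated cluster miRNAs.
#' @param cluster_group_log2fc Length-3 log2 shifts of cluster expression per
#'   subgroup, in the order `group_labels` (high / intermediate / low).
#' @param cluster_factor_sd SD (log2) of the shared per-sample latent factor
#'   loading all cluster members (and the host gene).
#' @param cluster_mean_log2cpm Target mean log2-CPM of cluster miRNAs in the
#'   highest-expressing subgroup.
#' @param host_loading Multiplier on the cluster factor and gradient for the
#'   host lncRNA (precursor transcript; wider dynamic range than the
#'   processed miRNAs).
#' @param n_true_pairs Planted regulatory miRNA:mRNA pairs (cluster miRNA x
#'   planted DE mRNA, each coupled through an independent latent variable).
#' @param coupling_strength Log2-scale coupling of a pair's miRNA (positive)
#'   and mRNA (negative) to its latent variable; the realized loadings are
#'   `0.4 * coupling_strength` on the miRNA and `(4/3) * coupling_strength`
#'   on the mRNA (see the methods vignette).
#' @param de_fraction,de_log2fc Fraction of mRNAs given a subgroup effect and
#'   its magnitude (sign random; the effect distinguishes the third subgroup
#'   from the other two).
#' @param db_true_recall Probability a true pair is listed in the database.
#' @param db_decoy_count Random decoy interactions added to the database.
#' @param group_labels Names of the three subgroups, highest cluster
#'   expression first.
#' @param seed Master seed; all stage generators derive from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = 13,
                             n_mrna = 15529,
                             n_mirna = 922,
                             lib_size_mrna = 4e7,
                             lib_size_mirna = 2.4e6,
                             dispersion = 0.1,
                             baseline_log2_sd = 2.5,
                             cluster_size = 53,
                             cluster_group_log2fc = c(0, -0.33, -0.66),
                             cluster_factor_sd = 0.25,
                             cluster_mean_log2cpm = 2.37,
                             host_loading = 3.5,
                             n_true_pairs = 75,
                             coupling_strength = 1.8,
                             de_fraction = 0.0129,
                             de_log2fc = 2,
                             db_true_recall = 0.8,
                             db_decoy_count = 20000,
                             group_labels = c("M-CLL-NS", "M-CLL-S", "U-CLL-S"),
                             seed = 1) {
  cfg <- list(
    n_per_group = n_per_group, n_mrna = n_mrna, n_mirna = n_mirna,
    lib_size_mrna = lib_size_mrna, lib_size_mirna = lib_size_mirna,
    dispersion = dispersion, baseline_log2_sd = baseline_log2_sd,
    cluster_size = cluster_size,
    cluster_group_log2fc = cluster_group_log2fc,
    cluster_factor_sd = cluster_factor_sd,
    cluster_mean_log2cpm = cluster_mean_log2cpm,
    host_loading = host_loading,
    n_true_pairs = n_true_pairs, coupling_strength = coupling_strength,
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    db_true_recall = db_true_recall, db_decoy_count = db_decoy_count,
    group_labels = group_labels, seed = seed
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  need_pos <- c(
    "n_per_group", "n_mrna", "n_mirna", "lib_size_mrna",
    "lib_size_mirna", "cluster_size", "de_log2fc"
  )
  for (f in need_pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("invalid config field: ", f)
    }
  }
  need_nonneg <- c(
    "dispersion", "baseline_log2_sd", "cluster_factor_sd",
    "n_true_pairs", "coupling_strength", "de_fraction",
    "db_decoy_count", "host_loading"
  )
  for (f in need_nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      stop("invalid config field: ", f)
    }
  }
  if (cfg$cluster_size > cfg$n_mirna) stop("invalid config field: cluster_size")
  if (length(cfg$cluster_group_log2fc) != 3) {
    stop("invalid config field: cluster_group_log2fc")
  }
  if (cfg$db_true_recall < 0 || cfg$db_true_recall > 1) {
    stop("invalid config field: db_true_recall")
  }
  if (cfg$n_true_pairs > cfg$n_mirna * cfg$n_mrna) {
    stop("invalid config field: n_true_pairs")
  }
  if (length(cfg$group_labels) != 3) stop("invalid config field: group_labels")
  if (cfg$de_fraction > 1) stop("invalid config field: de_fraction")
  invisible(cfg)
}

nb_draw <- function(mu, phi) {
  n <- length(mu)
  if (phi > 0) rnbinom(n, size = 1 / phi, mu = mu) else rpois(n, lambda = mu)
}

# Solve the baseline of a feature set so its expected CPM hits a target,
# given the summed relative abundance of the remaining features.
baseline_for_cpm <- function(target_log2cpm, n_members, sum_other) {
  p <- 2^target_log2cpm / 1e6
  if (n_members * p >= 1) stop("target CPM infeasible for this many members")
  log2(p * sum_other / (1 - n_members * p))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws mRNA and miRNA count matrices, sample metadata, genomic annotation
#' (cluster miRNAs and the host gene tiled inside the configured locus,
#' flanking features nearby, everything else on other chromosomes), a target
#' database, and a truth record of every planted structure. Output is
#' bit-identical for identical configurations.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_dataset`: a list with elements
#'   `mrna_counts`, `mirna_counts` (`count_matrix`), `metadata`,
#'   `annotation`, `locus`, `database`, `truth` and `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  validate_synthetic_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- 3 * cfg$n_per_group
    groups <- factor(rep(cfg$group_labels, each = cfg$n_per_group),
      levels = cfg$group_labels
    )
    sample_ids <- sprintf("CLL%02d", seq_len(n))
    metadata <- data.frame(
      sample_id = sample_ids, group = as.character(groups),
      stringsAsFactors = FALSE
    )

    mirna_ids <- sprintf("miR-syn-%04d", seq_len(cfg$n_mirna))
    mrna_ids <- sprintf("GENE%05d", seq_len(cfg$n_mrna))
    host_idx <- 1L
    mrna_ids[host_idx] <- "MEG3L-syn"

    # --- miRNA abundance model -------------------------------------------
    b_mi <- rnorm(cfg$n_mirna, 0, cfg$baseline_log2_sd)
    members <- sort(sample.int(cfg$n_mirna, cfg$cluster_size))
    bc <- baseline_for_cpm(
      cfg$cluster_mean_log2cpm, cfg$cluster_size,
      sum(2^b_mi[-members])
    )
    b_mi[members] <- bc + rnorm(cfg$cluster_size, 0, 0.3)
    frac_mi <- 2^b_mi / sum(2^b_mi)

    f_s <- rnorm(n, 0, cfg$cluster_factor_sd) # shared cluster factor
    shift_s <- cfg$cluster_group_log2fc[as.integer(groups)]
    # per-member gradient amplitude: members respond to the subgroup
    # gradient with heterogeneous strength (mean 1), so a subset shows
    # fold changes well beyond the locus average, as observed for
    # clustered miRNAs
    member_scale <- stats::rgamma(cfg$cluster_size, shape = 5, rate = 5)

    adj_mi <- matrix(0, cfg$n_mirna, n)
    adj_mi[members, ] <- member_scale %o% shift_s +
      rep(f_s, each = cfg$cluster_size)

    # --- mRNA abundance model --------------------------------------------
    b_mr <- rnorm(cfg$n_mrna, 0, cfg$baseline_log2_sd)
    b_mr[host_idx] <- baseline_for_cpm(5, 1, sum(2^b_mr[-host_idx]))
    frac_mr <- 2^b_mr / sum(2^b_mr)

    n_de <- round(cfg$de_fraction * cfg$n_mrna)
    # planted DE genes are mid-abundance (expected CPM in [1, 100]): low
    # enough that single coupled genes cannot distort library composition,
    # high enough to survive filtering
    cpmv <- frac_mr * 1e6
    pool <- setdiff(which(cpmv >= 1 & cpmv <= 100), host_idx)
    if (length(pool) < n_de) {
      extra <- setdiff(which(cpmv >= 1), c(host_idx, pool))
      pool <- c(pool, extra[order(cpmv[extra])])
    }
    if (n_de > length(pool)) n_de <- length(pool)
    de_idx <- sort(sample(pool, n_de))
    de_sign <- sample(c(1, -1), n_de, replace = TRUE)
    # regulatory targets of a down-gradient cluster run against it: genes
    # later chosen as pair partners are oriented opposite to the cluster's
    # shift in the effect arm
    target_sign <- if (cfg$cluster_group_log2fc[3] <= 0) 1 else -1

    adj_mr <- matrix(0, cfg$n_mrna, n)
    in_alt <- as.integer(groups) == 3L # third subgroup carries the DE effect
    adj_mr[host_idx, ] <- cfg$host_loading * (shift_s + f_s)

    # --- planted regulatory pairs ----------------------------------------
    n_pairs <- cfg$n_true_pairs
    max_pairs <- cfg$cluster_size * n_de
    if (n_pairs > 0 && max_pairs == 0) {
      stop("n_true_pairs > 0 requires planted DE mRNAs (de_fraction > 0)")
    }
    if (n_pairs > max_pairs) n_pairs <- max_pairs
    if (n_pairs > 0) {
      # matching-first sampling: each miRNA and gene is used once while the
      # pools last, then additional pairs reuse nodes (hubs). Under the
      # independent per-pair factor model, hub nodes accumulate variance
      # that attenuates each of their pairs, so hubs are kept to the
      # minimum the requested pair count forces.
      mi_order <- sample(members)
      gi_order <- sample(de_idx)
      n_match <- min(n_pairs, length(mi_order), length(gi_order))
      pair_mi <- mi_order[seq_len(n_match)]
      pair_gi <- gi_order[seq_len(n_match)]
      used <- paste(pair_mi, pair_gi)
      while (length(pair_mi) < n_pairs) {
        need <- n_pairs - length(pair_mi)
        cand_mi <- sample(members, need, replace = TRUE)
        cand_gi <- sample(de_idx, need, replace = TRUE)
        key <- paste(cand_mi, cand_gi)
        ok <- !(key %in% used) & !duplicated(key)
        pair_mi <- c(pair_mi, cand_mi[ok])
        pair_gi <- c(pair_gi, cand_gi[ok])
        used <- c(used, key[ok])
      }
      z <- matrix(rnorm(n_pairs * n), n_pairs, n)
      for (j in seq_len(n_pairs)) {
        adj_mi[pair_mi[j], ] <- adj_mi[pair_mi[j], ] +
          PAIR_LOADING_MIRNA * cfg$coupling_strength * z[j, ]
        adj_mr[pair_gi[j], ] <- adj_mr[pair_gi[j], ] -
          PAIR_LOADING_MRNA * cfg$coupling_strength * z[j, ]
      }
    } else {
      pair_mi <- integer(0)
      pair_gi <- integer(0)
    }
    if (n_pairs > 0) {
      de_sign[match(unique(pair_gi), de_idx)] <- target_sign
    }
    if (n_de > 0) {
      adj_mr[de_idx, in_alt] <- adj_mr[de_idx, in_alt] +
        de_sign * cfg$de_log2fc
    }

    # --- draw counts ------------------------------------------------------
    mu_mi <- cfg$lib_size_mirna * frac_mi * 2^adj_mi
    mu_mr <- cfg$lib_size_mrna * frac_mr * 2^adj_mr
    mirna_counts <- matrix(nb_draw(mu_mi, cfg$dispersion), cfg$n_mirna, n,
      dimnames = list(mirna_ids, sample_ids)
    )
    mrna_counts <- matrix(nb_draw(mu_mr, cfg$dispersion), cfg$n_mrna, n,
      dimnames = list(mrna_ids, sample_ids)
    )

    # --- annotation -------------------------------------------------------
    locus <- locus_definition("chr14", 100825000, 101070000,
      name = "syn-mir-cluster-14q32"
    )
    annotation <- synth_annotation(
      cfg, locus, mirna_ids, mrna_ids, members, host_idx
    )

    truth <- list(
      de_mrna = data.frame(
        feature_id = mrna_ids[de_idx],
        log2fc = de_sign * cfg$de_log2fc, stringsAsFactors = FALSE
      ),
      cluster_mirnas = mirna_ids[members],
      pairs = data.frame(
        mirna_id = mirna_ids[pair_mi], gene_id = mrna_ids[pair_gi],
        stringsAsFactors = FALSE
      ),
      host_gene = mrna_ids[host_idx]
    )

    database <- generate_target_database(
      truth$pairs, mirna_ids, mrna_ids,
      recall = cfg$db_true_recall, decoys = cfg$db_decoy_count,
      seed = (cfg$seed + 999983) %% 2147483647L
    )

    structure(
      list(
        mrna_counts = count_matrix(mrna_counts, "mRNA"),
        mirna_counts = count_matrix(mirna_counts, "miRNA"),
        metadata = metadata,
        annotation = annotation,
        locus = locus,
        database = database,
        truth = truth,
        config = cfg
      ),
      class = "synthetic_dataset"
    )
  })
}

# Cluster members tiled at fixed spacing inside the locus, host gene at its
# 5' end, a few flanking features within 400 kb outside, everything else on
# other chromosomes: makes locus-membership tests unambiguous.
synth_annotation <- function(cfg, locus, mirna_ids, mrna_ids, members,
                             host_idx) {
  spacing <- floor((locus$end - locus$start - 4000) / cfg$cluster_size)
  m_start <- locus$start + 2000 + (seq_len(cfg$cluster_size) - 1L) * spacing
  ann_mi <- data.frame(
    feature_id = mirna_ids, chrom = "", start = 0, end = 0, strand = "+",
    type = "miRNA", stringsAsFactors = FALSE
  )
  ann_mi$chrom[members] <- locus$chrom
  ann_mi$start[members] <- m_start
  ann_mi$end[members] <- m_start + 21

  ann_mr <- data.frame(
    feature_id = mrna_ids, chrom = "", start = 0, end = 0, strand = "+",
    type = "mRNA", stringsAsFactors = FALSE
  )
  ann_mr$chrom[host_idx] <- locus$chrom
  ann_mr$start[host_idx] <- locus$start + 100
  ann_mr$end[host_idx] <- locus$start + 1600

  other_chroms <- paste0("chr", c(1:13, 15:22))
  place_other <- function(ann, open, len) {
    k <- length(open)
    ann$chrom[open] <- sample(other_chroms, k, replace = TRUE)
    ann$start[open] <- round(runif(k, 1e6, 2e8))
    ann$end[open] <- ann$start[open] + len
    ann$strand[open] <- sample(c("+", "-"), k, replace = TRUE)
    ann
  }
  place_flank <- function(ann, idx, len) {
    k <- length(idx)
    side <- rep_len(c(-1, 1), k)
    pos <- round(runif(k, 2e4, 4e5))
    ann$chrom[idx] <- locus$chrom
    ann$start[idx] <- ifelse(side < 0, locus$start - pos, locus$end + pos)
    ann$end[idx] <- ann$start[idx] + len
    ann
  }
  open_mi <- setdiff(seq_along(mirna_ids), members)
  flank_mi <- utils::head(open_mi, min(6, length(open_mi)))
  ann_mi <- place_flank(ann_mi, flank_mi, 21)
  ann_mi <- place_other(ann_mi, setdiff(open_mi, flank_mi), 21)

  open_mr <- setdiff(seq_along(mrna_ids), host_idx)
  flank_mr <- utils::head(open_mr, min(10, length(open_mr)))
  ann_mr <- place_flank(ann_mr, flank_mr, 2000)
  ann_mr <- place_other(ann_mr, setdiff(open_mr, flank_mr), 2000)

  rbind(ann_mi, ann_mr)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    paste0(
      "synthetic_dataset: %d mRNAs x %d samples, %d miRNAs\n",
      "  cluster: %d miRNAs in %s\n",
      "  planted: %d DE mRNAs, %d regulatory pairs; database: %d entries\n"
    ),
    nrow(x$mrna_counts$counts), ncol(x$mrna_counts$counts),
    nrow(x$mirna_counts$counts),
    length(x$truth$cluster_mirnas), format(x$locus),
    nrow(x$truth$de_mrna), nrow(x$truth$pairs), nrow(x$database)
  ))
  invisible(x)
}

#' Generate a target-interaction database from planted pairs
#'
#' Each true pair is listed with probability `recall`; `decoys` additional
#' interactions are sampled uniformly without replacement from all non-true
#' (miRNA, gene) pairs. True entries carry source `"synthetic-curated"` and
#' score 85; decoys carry one of two predicted-source tags and a random
#' score.
#'
#' @param truth_pairs Data frame with columns `mirna_id`, `gene_id` (may be
#'   empty).
#' @param mirna_universe,mrna_universe Character vectors of feature ids.
#' @param recall Probability in `[0, 1]` that a true pair is listed.
#' @param decoys Number of decoy entries (must not exceed the number of
#'   available non-true pairs).
#' @param seed Integer seed.
#' @return A [target_database()].
#' @export
generate_target_database <- function(truth_pairs, mirna_universe,
                                     mrna_universe, recall, decoys, seed = 1) {
  if (recall < 0 || recall > 1) stop("recall must lie in [0, 1]")
  if (decoys < 0) stop("decoys must be >= 0")
  m <- length(mirna_universe)
  g <- length(mrna_universe)
  truth_lin <- integer(0)
  if (nrow(truth_pairs) > 0) {
    mi <- match(truth_pairs$mirna_id, mirna_universe)
    gi <- match(truth_pairs$gene_id, mrna_universe)
    if (any(is.na(mi)) || any(is.na(gi))) {
      stop("truth pairs outside the feature universes")
    }
    truth_lin <- (gi - 1) * m + mi
  }
  total <- as.double(m) * g
  if (decoys > total - length(truth_lin)) {
    stop("decoys exceed the number of available non-true pairs")
  }
  withr::with_seed(seed, {
    kept <- if (length(truth_lin) > 0) {
      truth_pairs[rbinom(nrow(truth_pairs), 1, recall) == 1, , drop = FALSE]
    } else {
      truth_pairs
    }
    decoy_lin <- integer(0)
    while (length(decoy_lin) < decoys) {
      need <- decoys - length(decoy_lin)
      cand <- sample(total, min(total, need + length(truth_lin) + 100L))
      cand <- setdiff(cand, c(truth_lin, decoy_lin))
      decoy_lin <- c(decoy_lin, utils::head(cand, need))
    }
    entries <- data.frame(
      mirna_id = character(0), gene_id = character(0),
      source = character(0), score = numeric(0), stringsAsFactors = FALSE
    )
    if (nrow(kept) > 0) {
      entries <- rbind(entries, data.frame(
        mirna_id = kept$mirna_id, gene_id = kept$gene_id,
        source = "synthetic-curated", score = 85, stringsAsFactors = FALSE
      ))
    }
    if (length(decoy_lin) > 0) {
      mi <- (decoy_lin - 1) %% m + 1
      gi <- (decoy_lin - 1) %/% m + 1
      entries <- rbind(entries, data.frame(
        mirna_id = mirna_universe[mi], gene_id = mrna_universe[gi],
        source = sample(c("synthetic-predicted-A", "synthetic-predicted-B"),
          length(decoy_lin),
          replace = TRUE
        ),
        score = sample(50:100, length(decoy_lin), replace = TRUE),
        stringsAsFactors = FALSE
      ))
    }
    target_database(entries)
  })
}

#' Write a synthetic dataset to a fixture bundle
#'
#' Counts as TSV and MatrixMarket (with feature/sample sidecar files),
#' metadata and database as TSV, annotation as 6-column BED (converted to
#' 0-based half-open on write), truth tables as TSV and the configuration as
#' YAML.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param formats Count formats to write: subset of `c("tsv", "mtx")`.
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(ds, dir, formats = c("tsv", "mtx")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (what in c("mrna", "mirna")) {
    cm <- ds[[paste0(what, "_counts")]]
    if ("tsv" %in% formats) {
      p <- file.path(dir, paste0(what, "_counts.tsv"))
      write_counts(cm, p, format = "tsv")
      paths[paste0(what, "_counts_tsv")] <- p
    }
    if ("mtx" %in% formats) {
      p <- file.path(dir, paste0(what, "_counts.mtx"))
      write_counts(cm, p, format = "mtx")
      paths[paste0(what, "_counts_mtx")] <- p
    }
  }
  p <- file.path(dir, "metadata.tsv")
  utils::write.table(ds$metadata, p,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths["metadata"] <- p
  p <- file.path(dir, "annotation.bed")
  write_bed_annotation(ds$annotation, p)
  paths["annotation"] <- p
  p <- file.path(dir, "database.tsv")
  write_target_database(ds$database, p)
  paths["database"] <- p
  for (tn in c("de_mrna", "pairs")) {
    p <- file.path(dir, paste0("truth_", tn, ".tsv"))
    utils::write.table(ds$truth[[tn]], p,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths[paste0("truth_", tn)] <- p
  }
  p <- file.path(dir, "truth_cluster_mirnas.tsv")
  utils::write.table(
    data.frame(mirna_id = ds$truth$cluster_mirnas),
    p,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths["truth_cluster_mirnas"] <- p
  p <- file.path(dir, "config.yaml")
  yaml::write_yaml(
    c(unclass(ds$config), list(locus = format(ds$locus))), p
  )
  paths["config"] <- p
  invisible(paths)
}
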