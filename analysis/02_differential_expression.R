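#!/usr/bin/env Rscript
# Stage 2: filtering, normalization and differential expression.
#
# Filters low-count features (CPM >= 1 in at least 13 samples), computes TMM
# factors, and fits the negative-binomial likelihood-ratio test for the
# U-CLL-S vs M-CLL contrast on both the mRNA and miRNA matrices. Writes DE
# tables, volcano-ready tables and PCA scores under results/de/.

suppressPackageStartupMessages(library(mirlink))

dir.create("results/de", recursive = TRUE, showWarnings = FALSE)
meta <- read_metadata("results/data/metadata.tsv")
arm <- factor(ifelse(meta$group == "U-CLL-S", "alt", "ref"),
  levels = c("ref", "alt")
)

for (what in c("mrna", "mirna")) {
  counts <- read_counts(
    sprintf("results/data/%s_counts.tsv", what),
    feature_type = if (what == "mrna") "mRNA" else "miRNA"
  )
  filt <- filter_low_counts(counts, min_cpm = 1, min_samples = 13)
  rep <- filt$report
  message(sprintf(
    "%s: %d features; %d not detectable, %d low-count, %d retained",
    what, rep$n_total, rep$n_undetectable, rep$n_low, rep$n_retained
  ))
  norm <- tmm_factors(filt$counts)
  de <- nb_lrt(filt$counts, arm, contrast = c("ref", "alt"), norm = norm)
  de <- volcano_categories(de)
  write.table(de, sprintf("results/de/de_%s.tsv", what),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  n_up <- sum(de$direction == "up")
  n_down <- sum(de$direction == "down")
  message(sprintf(
    "%s DE (FDR <= 0.05, |log2FC| >= 1): %d up, %d down in U-CLL-S",
    what, n_up, n_down
  ))
  # exploratory PCA on log2-CPM
  l2 <- cpm(filt$counts, norm, log2 = TRUE)
  pc <- pca_svd(t(l2), n_components = 5)
  write.table(
    data.frame(sample_id = rownames(pc$scores), group = meta$group, pc$scores),
    sprintf("results/de/pca_%s_scores.tsv", what),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  message(sprintf(
    "%s PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
    what, 100 * pc$var_explained[1], 100 * pc$var_explained[2]
  ))
}
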