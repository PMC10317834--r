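#!/usr/bin/env Rscript
# Stage 3: expression analytics for the clustered miRNA locus.
#
# Assigns miRNAs to the locus by midpoint, summarises locus-wide expression
# per subgroup (with exact Wilcoxon rank-sum tests), builds the per-member
# ribbon table and the locus +/- 500 kb co-expression matrix, correlates the
# locus mean with the host lncRNA, and clusters samples by member profiles
# (k = 3, labelled high/intermediate/low). Writes under results/locus/.

suppressPackageStartupMessages(library(mirlink))

dir.create("results/locus", recursive = TRUE, showWarnings = FALSE)
meta <- read_metadata("results/data/metadata.tsv")
ann <- read_bed_annotation("results/data/annotation.bed")
locus <- parse_locus("chr14:100,825,000-101,070,000", name = "mir-cluster-14q32")

mirna <- read_counts("results/data/mirna_counts.tsv", feature_type = "miRNA")
mrna <- read_counts("results/data/mrna_counts.tsv", feature_type = "mRNA")
filt_i <- filter_low_counts(mirna, 1, 13)$counts
filt_m <- filter_low_counts(mrna, 1, 13)$counts
l2_i <- cpm(filt_i, tmm_factors(filt_i), log2 = TRUE)
l2_m <- cpm(filt_m, tmm_factors(filt_m), log2 = TRUE)

members_all <- assign_locus_membership(ann, locus)
members <- intersect(members_all, rownames(l2_i))
host <- intersect(members_all, rownames(l2_m))
message(length(members), " locus miRNAs expressed; host gene(s): ",
  paste(host, collapse = ", "))

summ <- locus_group_summary(l2_i, members, meta$group)
print(summ)
print(summ$tests)
write.table(
  data.frame(sample_id = names(summ$sample_means), group = meta$group,
    mean_log2cpm = summ$sample_means),
  "results/locus/sample_means.tsv", sep = "\t", quote = FALSE, row.names = FALSE
)
write.table(summ$tests, "results/locus/group_tests.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
dir_tab <- summ$member_direction
message(sprintf(
  "%.1f%% of members under-expressed in U-CLL-S vs M-CLL-NS",
  100 * dir_tab$frac_members_lower_in_b[dir_tab$group_a == "M-CLL-NS" &
    dir_tab$group_b == "U-CLL-S"]
))

write.table(
  ribbon_summary(l2_i, ann, members, meta$group),
  "results/locus/ribbon.tsv", sep = "\t", quote = FALSE, row.names = FALSE
)

l2_all <- rbind(l2_i, l2_m)
coex <- coexpression_matrix(l2_all, ann, locus, window = 5e5)
write.table(
  data.frame(feature_id = rownames(coex$r), round(coex$r, 6),
    check.names = FALSE),
  "results/locus/coexpression_r.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE
)
in_r <- coex$r[coex$is_member, coex$is_member]
out_r <- coex$r[coex$is_member, !coex$is_member]
message(sprintf(
  "median within-locus r = %.2f; median |r| to flanking features = %.2f",
  median(in_r[upper.tri(in_r)], na.rm = TRUE),
  median(abs(out_r), na.rm = TRUE)
))
if (length(host) > 0) {
  hr <- locus_vs_gene_correlation(summ$sample_means, l2_m[host[1], ])
  message(sprintf("locus mean vs %s: r = %.2f (p = %.2g)",
    host[1], hr$estimate, hr$p_value))
}

cl <- cluster_samples(l2_i, members, meta$group, k = 3, seed = 1)
print(cl$contingency)
write.table(as.data.frame(cl$contingency), "results/locus/kmeans_contingency.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
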