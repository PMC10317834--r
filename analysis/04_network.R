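#!/usr/bin/env Rscript
# Stage 4: the miRNA:mRNA anti-correlation network.
#
# Takes the top 200 signature mRNAs (FDR <= 0.05, |log2FC| >= 1, ranked by
# p), correlates every locus miRNA against them, keeps significant negative
# pairs (BH-adjusted p <= 0.05), intersects with the target database
# (>= 1 source), assembles the bipartite network, and exports SIF, GraphML
# and edge TSV plus degree tables under results/network/.

suppressPackageStartupMessages(library(mirlink))

dir.create("results/network", recursive = TRUE, showWarnings = FALSE)
meta <- read_metadata("results/data/metadata.tsv")
ann <- read_bed_annotation("results/data/annotation.bed")
locus <- parse_locus("chr14:100,825,000-101,070,000")
db <- read_target_database("results/data/database.tsv")

mirna <- read_counts("results/data/mirna_counts.tsv", feature_type = "miRNA")
mrna <- read_counts("results/data/mrna_counts.tsv", feature_type = "mRNA")
filt_i <- filter_low_counts(mirna, 1, 13)$counts
filt_m <- filter_low_counts(mrna, 1, 13)$counts
l2_i <- cpm(filt_i, tmm_factors(filt_i), log2 = TRUE)
l2_m <- cpm(filt_m, tmm_factors(filt_m), log2 = TRUE)

de_m <- read.delim("results/de/de_mrna.tsv", stringsAsFactors = FALSE)
de_i <- read.delim("results/de/de_mirna.tsv", stringsAsFactors = FALSE)
signature <- suppressWarnings(
  select_signature(de_m, fdr_max = 0.05, min_abs_log2fc = 1, top_n = 200)
)
members <- intersect(assign_locus_membership(ann, locus), rownames(l2_i))
message(length(signature), " signature mRNAs x ", length(members),
  " locus miRNAs")

pairs <- correlate_pairs(l2_i[members, ], l2_m[signature, ])
neg <- filter_negative_significant(pairs, p_adj_max = 0.05)
supported <- intersect_with_databases(neg, db, min_sources = 1)
message(nrow(pairs), " pairs tested; ", nrow(neg),
  " significant negative; ", nrow(supported), " database-supported")

net <- suppressWarnings(build_network(supported, de_mirna = de_i, de_mrna = de_m))
export_network(net, "results/network/network.sif", "sif")
export_network(net, "results/network/network.graphml", "graphml")
export_network(net, "results/network/network_edges.tsv", "edge-tsv")
deg <- degree_summary(net)
write.table(deg$mirna, "results/network/degree_mirna.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
write.table(deg$mrna, "results/network/degree_mrna.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
if (nrow(deg$mirna) > 0) {
  top <- head(deg$mirna, 5)
  message("highest-degree miRNAs: ",
    paste(sprintf("%s (%d)", top$feature_id, top$degree), collapse = ", "))
}
cov <- fraction_of_signature_targeted(net, signature)
message(sprintf(
  "%d of %d signature mRNAs (%.1f%%) carry at least one network edge",
  cov$covered, length(signature), 100 * cov$fraction
))
writeLines(
  sprintf("signature\t%d\ncovered\t%d\nfraction\t%.6f",
    length(signature), cov$covered, cov$fraction),
  "results/network/signature_coverage.tsv"
)
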