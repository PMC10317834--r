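# mirlink

Integrative miRNA:mRNA transcriptomics for cohorts split into disease
subgroups — built for the situation where a co-regulated genomic miRNA
cluster (a polycistronic locus such as an imprinted DLK1-DIO3-type region)
is suspected of shaping a disease-subgroup mRNA signature, and the
evidence must come from expression data plus target-prediction databases
rather than perturbation experiments.

The package implements the full analysis chain:

1. **Differential expression** — count filtering, TMM normalization, and a
   per-feature negative-binomial likelihood-ratio test
   (var = μ + φμ², full model = group factor, null = intercept, LRT on
   χ²₁), with BH-adjusted FDR and prior-count-moderated log₂ fold changes.
   Signatures are selected at FDR ≤ 0.05, |log₂FC| ≥ 1, ranked by p, top N.
2. **Locus analytics** — interval membership by midpoint, locus-wide
   expression summaries per subgroup with exact Wilcoxon rank-sum tests,
   per-member median/IQR ribbon tables in genomic order, all-pairs
   co-expression with flanking features, and k-means sample clustering
   with deterministic high/intermediate/low labels.
3. **Anti-correlation network** — all-pairs Pearson correlation between
   miRNAs and signature mRNAs on log₂-CPM, selection of significant
   negative pairs (BH-adjusted p ≤ 0.05, r < 0), intersection with
   target-interaction databases (≥ 1 source), bipartite igraph assembly,
   degree summaries, and SIF/GraphML/TSV export.
4. **Resampling enrichment** — is the number of database-supported
   interactions between the locus miRNAs and the signature larger than for
   size-matched random sets? B = 50,000 draws from the expressed-feature
   universes; reported as the empirical p-value
   (1 + #{null ≥ observed})/(B + 1) alongside the literal one-sample t
   construction.
5. **Synthetic cohorts** — a generator that plants a gradient-bearing
   miRNA cluster, a co-expressed host lncRNA, differentially expressed
   mRNAs, negatively coupled miRNA:mRNA pairs and a decoy-laced target
   database, so every stage above is testable against known truth.

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `05_enrichment.R`) that runs the whole study on the
default synthetic cohort and writes its tables under `results/`.

## Worked example

```r
library(mirlink)

cfg <- synthetic_config(n_mrna = 3000, de_fraction = 200 / 3000,
                        db_decoy_count = 4000, seed = 7)
ds <- generate_dataset(cfg)
ds
#> synthetic_dataset: 3000 mRNAs x 39 samples, 922 miRNAs
#>   cluster: 53 miRNAs in chr14:100825000-101070000
#>   planted: 200 DE mRNAs, 75 regulatory pairs; database: 4062 entries

norm <- tmm_factors(ds$mirna_counts)
l2 <- cpm(ds$mirna_counts, norm, log2 = TRUE)
summ <- locus_group_summary(l2, ds$truth$cluster_mirnas, ds$metadata$group)
summ
#> locus_summary: 53 members
#> group means (log2-CPM):
#> M-CLL-NS  M-CLL-S  U-CLL-S
#>    2.294    2.010    1.572
subset(summ$tests, group_a == "M-CLL-NS" & group_b == "U-CLL-S")
#>    group_a group_b statistic      p_value                    method
#> 2 M-CLL-NS U-CLL-S       158 3.749784e-05 Wilcoxon rank-sum (exact)

res <- run_enrichment(ds$truth$cluster_mirnas, ds$truth$de_mrna$feature_id,
                      ds$database,
                      rownames(ds$mirna_counts$counts),
                      rownames(ds$mrna_counts$counts),
                      B = 10000, seed = 1)
res
#> enrichment_result: observed = 81, null mean = 15.57 (sd 3.90, B = 10000)
#>   p_empirical = 0.0001, one-sample t p = 0
```

Reading the output: the planted cluster shows the high → intermediate →
low subgroup gradient (group means 2.29 / 2.01 / 1.57 log₂-CPM) and the
extreme-group difference is significant by the exact rank-sum test
(p ≈ 3.7 × 10⁻⁵). The cluster-to-signature interaction count (81) sits
far above the resampling null (mean 15.6), so the empirical p hits its
floor at 1/(B + 1).

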