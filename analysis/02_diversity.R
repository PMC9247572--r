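#!/usr/bin/env Rscript
# Diversity and composition: filter + TMM, alpha diversity and rarefaction,
# Bray-Curtis beta diversity with PCoA, PERMANOVA on state, and the
# rank-sum differential abundance screen.

suppressMessages(library(microdrivers))

tab <- read_count_table("results/data/counts.tsv", "results/data/metadata.tsv")
out <- "results/diversity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

filtered <- filter_asvs(tab)          # >=20% prevalence OR >2.5% mean rel. abundance
norm <- tmm_normalize(filtered)
rel <- to_relative(filtered)
states <- filtered$metadata$state

alpha <- alpha_diversity(filtered)
write.table(alpha, file.path(out, "alpha_diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (idx in c("richness", "shannon")) {
  w <- wilcox.test(alpha[[idx]][states == "BT"], alpha[[idx]][states == "AT"])
  message(sprintf("%s BT vs AT: W = %.0f, p = %.3f", idx, w$statistic, w$p.value))
}

rare <- rarefaction_curve(filtered, depths = c(500, 2000, 5000, 10000, 16589))
write.table(rare, file.path(out, "rarefaction.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

d <- bray_curtis(rel)
write.table(as.matrix(d), file.path(out, "bray_curtis.tsv"), sep = "\t",
            quote = FALSE)
ord <- pcoa(d)
write.table(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates[, 1:2]),
            file.path(out, "pcoa_coordinates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
pv <- permanova(d, states, n_permutations = 999, seed = 11)
message(sprintf("PERMANOVA state: F = %.2f, R2 = %.3f, p = %.3f",
                pv$pseudo_F, pv$R2, pv$p))

diff <- rank_sum_differential(rel, states)
write.table(diff[order(diff$p), ], file.path(out, "differential_abundance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("differential: %d ASVs at BH-adjusted p < 0.05 (top: %s)",
                sum(diff$p_adj < 0.05),
                paste(head(diff$asv_id[order(diff$p_adj)], 3), collapse = ", ")))
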