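#!/usr/bin/env Rscript
# Co-occurrence networks per state (SparCC + permutation edge significance,
# |rho| > 0.3 and p < 0.05), greedy modules, summary metrics, indicator
# species, the NetShift-style BT-vs-AT node comparison with driver calls,
# and the provenance-tagged common subnetwork.

suppressMessages(library(microdrivers))

tab <- read_count_table("results/data/counts.tsv", "results/data/metadata.tsv")
out <- "results/networks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

filtered <- filter_asvs(tab)
states <- filtered$metadata$state
rel <- to_relative(filtered)

nets <- list()
top_n <- 150 # networks on the dominant community, as co-occurrence analyses do
for (st in c("BT", "AT")) {
  x <- filtered$counts[, states == st, drop = FALSE]
  x <- x[rowSums(x) > 0, , drop = FALSE]
  rel_mean <- rowMeans(sweep(x, 2, pmax(colSums(x), 1), "/"))
  x <- x[order(-rel_mean)[seq_len(min(top_n, nrow(x)))], , drop = FALSE]
  rho <- sparcc(x, n_iterations = 10, seed = 31)
  p <- edge_significance(x, rho, n_bootstraps = 30, seed = 32,
                         n_iterations = 10)
  net <- build_network(rho, p, rho_min = 0.3, alpha = 0.05)
  net <- detect_modules(net, seed = 33)
  nets[[st]] <- net
  m <- network_metrics(net)
  message(sprintf(
    "[%s] %d nodes, %d edges, ave degree %.2f, APL %.2f, density %.3f, mean betweenness %.3f, %d modules (Q = %.2f)",
    st, m$nodes, m$edges, m$ave_degree, m$ave_path_length, m$density,
    m$betweenness, length(unique(net$modules$module)), attr(net$modules, "Q")))
  write_network(net, file.path(out, sprintf("network_%s.tsv", st)))
  write.table(m, file.path(out, sprintf("metrics_%s.tsv", st)), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

ind <- indicator_species(rel, states, n_permutations = 1000, seed = 34)
sig <- ind[ind$significant, ]
message(sprintf("indicator species: %d significant (BT %d / AT %d)",
                nrow(sig), sum(sig$state == "BT"), sum(sig$state == "AT")))
write.table(ind, file.path(out, "indicator_species.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ns <- netshift_compare(nets$BT, nets$AT, nesh_quantile = 0.9)
drivers <- ns$asv_id[ns$is_driver]
message(sprintf("netshift: %d common-subnetwork nodes, %d drivers; top by DelBet: %s",
                nrow(ns), length(drivers),
                paste(head(ns$asv_id, 5), collapse = ", ")))
write.table(as.data.frame(ns), file.path(out, "netshift_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cs <- common_subnetwork(nets$BT, nets$AT)
write.table(cs$edges, file.path(out, "common_subnetwork.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("common subnetwork: %s",
                paste(names(table(cs$edges$tag)), table(cs$edges$tag),
                      collapse = ", ")))
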