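#!/usr/bin/env Rscript
# State classification and covariate regression: random forest on
# TMM-normalized z-scored abundances (MDA/MDG importances, held-out ROC/AUC)
# and the two-step covariate model for the focal ASV: all-subsets screening
# on adjusted R^2, then a negative-binomial fit with bootstrap significance.

suppressMessages(library(microdrivers))

tab <- read_count_table("results/data/counts.tsv", "results/data/metadata.tsv")
out <- "results/models"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

filtered <- filter_asvs(tab)
norm <- tmm_normalize(filtered)
states <- filtered$metadata$state

rf <- rf_classify(norm, states, n_trees = 500, train_fraction = 0.8, seed = 41)
message(sprintf("random forest: held-out AUC = %.3f; top 5 by MDA: %s",
                rf$auc, paste(head(rf$top_features, 5), collapse = ", ")))
write.table(rf$importance[order(rf$importance$rank_mda), ],
            file.path(out, "rf_importance.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rf$roc, file.path(out, "rf_roc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# covariate regression on the focal ASV's before-treatment abundance
focal <- "ASV30"
bt <- tab$metadata$state == "BT"
y <- tab$counts[focal, bt]
covs <- c("age", "height", "weight", "education", "flavor", "fruit_veg",
          "smoking", "drinking", "exercise", "sleep")
X <- tab$metadata[bt, covs]

subsets <- all_subsets(y, X, max_size = 4)
write.table(subsets[order(-subsets$adj_r2), ],
            file.path(out, "all_subsets.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
best <- subsets$subset[which.max(subsets$adj_r2)]
message(sprintf("all-subsets: best model {%s} (adj R2 = %.3f)",
                best, max(subsets$adj_r2)))

vars <- strsplit(best, ",", fixed = TRUE)[[1]]
fit <- negbin_glm(y, X[, vars, drop = FALSE], n_bootstrap = 9999, seed = 42)
print(fit)
write.table(fit$coefficients, file.path(out, "negbin_coefficients.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(focal_asv = focal, auc = rf$auc, selected = vars,
       dispersion = fit$dispersion,
       p_boot = setNames(as.list(fit$coefficients$p_boot),
                         fit$coefficients$term)),
  file.path(out, "models_summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("wrote ", file.path(out, "models_summary.json"))
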