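#!/usr/bin/env Rscript

# Step 3 — model building by randomized search.
#
# Splits the cohort 75/25, then for each of the eight classifier families
# draws 100 random pipeline configurations (selection levels, PCA variance
# target, family hyperparameters) and scores each by stratified five-fold
# cross-validated AUC on the training set. The winner is refitted on the
# full training set. The per-configuration log goes to scratch/, the
# per-family summary to results/.

suppressPackageStartupMessages(library(plaqueomics))

seed <- 1L
iterations <- 100L

tab <- read.csv("scratch/features.csv", check.names = FALSE,
                stringsAsFactors = FALSE)
feat <- as.matrix(tab[, feature_names()$feature])
y <- tab$label_advanced

sp <- split_train_validation(nrow(tab), 0.75, seed = seed)
cat("Split:", length(sp$train), "training /", length(sp$validation),
    "validation cross sections\n")

t0 <- Sys.time()
res <- run_search(feat[sp$train, ], y[sp$train], iterations = iterations,
                  seed = seed)
cat("Evaluated", nrow(res$log), "configurations in",
    round(as.numeric(Sys.time() - t0, units = "mins"), 1), "min\n")

write.csv(res$log, "scratch/search_log.csv", row.names = FALSE)

fam_best <- merge(res$per_family,
                  res$log[res$per_family$best_row,
                          c("family", "fpr_alpha", "fwer_alpha",
                            "pca_var_fraction", "params")],
                  by = "family")
fam_best <- fam_best[order(-fam_best$mean_cv_auc), ]
write.csv(fam_best, "results/model_search.csv", row.names = FALSE)
print(fam_best[, c("family", "mean_cv_auc")], row.names = FALSE)
cat("Best model:", res$best$family, "with mean CV AUC",
    round(res$best$mean_cv_auc, 3), "\n")

saveRDS(list(search = res, split = sp), "scratch/search_result.rds")
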