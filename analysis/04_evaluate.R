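#!/usr/bin/env Rscript

# Step 4 — validation-set evaluation.
#
# Applies the training-fitted winning pipeline unchanged to the held-out
# validation cross sections and compares it against the visual-pattern
# baseline and the two histogram baselines (low-attenuation area < 30 HU,
# mean HU), each scored by a univariate logistic model fitted on the
# training rows. ROC curves are compared pairwise with the DeLong test.

suppressPackageStartupMessages(library(plaqueomics))

tab <- read.csv("scratch/features.csv", check.names = FALSE,
                stringsAsFactors = FALSE)
state <- readRDS("scratch/search_result.rds")
sp <- state$split
feat <- as.matrix(tab[, feature_names()$feature])
y <- tab$label_advanced
tr <- sp$train; va <- sp$validation

roc_ml <- evaluate_validation(state$search, feat[va, ], y[va])
roc_pat <- univariate_logistic_baseline(tab$label_pattern[tr], y[tr],
                                        tab$label_pattern[va], y[va])
roc_low <- univariate_logistic_baseline(tab$base_lowatt_area[tr], y[tr],
                                        tab$base_lowatt_area[va], y[va])
roc_hu <- univariate_logistic_baseline(tab$base_mean_hu[tr], y[tr],
                                       tab$base_mean_hu[va], y[va])

rocs <- list(radiomics_ml = roc_ml, visual_pattern = roc_pat,
             low_attenuation_area = roc_low, mean_hu = roc_hu)
perf <- data.frame(
  model = names(rocs),
  auc = vapply(rocs, function(r) r$auc, numeric(1)),
  ci_lower = vapply(rocs, function(r) r$ci[1], numeric(1)),
  ci_upper = vapply(rocs, function(r) r$ci[2], numeric(1)))
write.csv(perf, "results/validation_performance.csv", row.names = FALSE)
print(perf, row.names = FALSE)

cmps <- lapply(names(rocs)[-1], function(nm) {
  cmp <- compare_delong(roc_ml, rocs[[nm]])
  data.frame(comparison = paste0("radiomics_ml_vs_", nm),
             auc_difference = cmp$diff, z = cmp$z, p = cmp$p,
             degenerate = cmp$degenerate)
})
cmps <- do.call(rbind, cmps)
write.csv(cmps, "results/delong_comparisons.csv", row.names = FALSE)
print(cmps, row.names = FALSE)

# the training/validation class balance, as a chi-square check
bal <- table(split = rep(c("train", "validation"),
                         c(length(tr), length(va))),
             advanced = y[c(tr, va)])
chi <- chi_square_balance(bal)
cat(sprintf("Class balance across splits: chi2 = %.3f, p = %.3f\n",
            chi$statistic, chi$p))
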