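#!/usr/bin/env Rscript

# Step 2 — radiomic feature extraction.
#
# Reads every NRRD image/mask pair written by step 1 and computes the full
# 1919-parameter radiomic vector per cross section (44 first-order
# statistics, 684 co-occurrence, 66 run-length, 1125 surface/fractal
# geometry features) plus the two histogram baselines (low-attenuation area
# below 30 HU and mean HU). The lesion-by-feature table goes to
# scratch/features.csv; a block summary goes to results/.

suppressPackageStartupMessages(library(plaqueomics))

cohort_dir <- "scratch/cohort"
labels <- read.csv(file.path(cohort_dir, "labels.csv"),
                   stringsAsFactors = FALSE)
cat("Reading", nrow(labels), "lesions from", cohort_dir, "\n")

lesions <- lapply(labels$lesion_id, function(id)
  read_lesion(file.path(cohort_dir, paste0(id, "_img.nrrd")),
              file.path(cohort_dir, paste0(id, "_msk.nrrd")),
              lesion_id = id))

t0 <- Sys.time()
tab <- extract_cohort(lesions, labels)
cat("Extracted", sum(names(tab) %in% feature_names()$feature),
    "radiomic features (+2 histogram baselines) for", nrow(tab),
    "lesions in", round(as.numeric(Sys.time() - t0, units = "mins"), 1),
    "min\n")

write.csv(tab, "scratch/features.csv", row.names = FALSE)

dict <- feature_names()
blocks <- as.data.frame(table(dict$block))
names(blocks) <- c("block", "n_features")
write.csv(blocks, "results/feature_blocks.csv", row.names = FALSE)
print(blocks)
stopifnot(sum(blocks$n_features) == 1919L)
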