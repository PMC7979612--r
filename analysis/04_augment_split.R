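#!/usr/bin/env Rscript
# Balance the 54/6 cohort with MWMOTE and split 0.7:0.3 stratified, the
# order used for the staging analysis (augment, then split). Reads
# results/features.csv and results/cohort.csv from the previous steps.

suppressMessages(library(ildradiomics))
seed <- 42

feats <- read.csv("results/features.csv", check.names = FALSE)
coh <- read_cohort_csv("results/cohort.csv")
stopifnot(identical(feats$patient_id, coh$patient_id))
X <- as.matrix(feats[, -1])
y <- factor(ifelse(coh$gap_stage_true == 1, "GAP1", "GAP2"),
            levels = c("GAP1", "GAP2"))

cat(sprintf("Input classes: %s (imbalance ratio %.2f)\n",
            paste(sprintf("%s=%d", names(table(y)), table(y)), collapse = ", "),
            imbalance_ratio(y)))
aug <- mwmote_oversample(X, y, augmentation_config(seed = seed + 10))
cat(sprintf("After MWMOTE: %s (%d synthetics)\n",
            paste(sprintf("%s=%d", names(table(aug$y_aug)), table(aug$y_aug)),
                  collapse = ", "),
            nrow(aug$provenance)))

sp <- stratified_split(nrow(aug$X_aug), aug$y_aug, 0.7, seed = seed + 11)
cat(sprintf("Split: train %d (%s) / test %d\n", length(sp$train),
            paste(table(aug$y_aug[sp$train]), collapse = "+"),
            length(sp$test)))

out <- data.frame(sample_id = rownames(aug$X_aug),
                  class = aug$y_aug,
                  split = ifelse(seq_len(nrow(aug$X_aug)) %in% sp$train,
                                 "train", "test"),
                  aug$X_aug, check.names = FALSE)
write.csv(out, "results/augmented_features.csv", row.names = FALSE)
jsonlite::write_json(aug$provenance, "results/mwmote_provenance.json",
                     dataframe = "rows", pretty = TRUE)
cat("Wrote results/augmented_features.csv and results/mwmote_provenance.json\n")
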