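#!/usr/bin/env Rscript
# The statistical core on the augmented training data: train-fitted
# z-scoring, Boruta shadow-feature selection, correlation clustering at
# r >= 0.60 with Gini representatives, logistic models compared by AIC,
# bootstrapped ROC on train / test / original data and 10-fold CV of the
# best model.

suppressMessages(library(ildradiomics))
seed <- 42

dat <- read.csv("results/augmented_features.csv", check.names = FALSE)
feats <- read.csv("results/features.csv", check.names = FALSE)
coh <- read_cohort_csv("results/cohort.csv")
y_all <- factor(dat$class, levels = c("GAP1", "GAP2"))
X_all <- as.matrix(dat[, -(1:3)])
train <- dat$split == "train"
y_orig <- factor(ifelse(coh$gap_stage_true == 1, "GAP1", "GAP2"),
                 levels = c("GAP1", "GAP2"))

zs <- suppressWarnings(zscore_standardize(
  X_all[train, , drop = FALSE],
  test = X_all[!train, , drop = FALSE],
  original = as.matrix(feats[, -1])[, colnames(X_all), drop = FALSE]
))
y_train <- y_all[train]; y_test <- y_all[!train]

cfg <- selection_config(boruta_max_runs = 60, n_trees = 300, seed = seed + 20)
sel <- select_features(zs$train, y_train, cfg)
cat(sprintf("Boruta confirmed %d of %d features; %d correlation clusters\n",
            length(sel$confirmed), ncol(zs$train),
            length(unique(sel$clusters))))
cat("Cluster representatives:\n")
print(unname(sel$representatives))

reps <- unname(sel$representatives)
if (length(reps) == 0) stop("no features confirmed - nothing to model")
singles <- fit_logistic_aic(zs$train, y_train, as.list(reps))
cat("\nSingle-feature models by AIC:\n")
print(singles[, c("terms", "aic", "separation")], digits = 5)

top <- unique(unlist(utils::head(strsplit(singles$terms, " \\+ "), 3)))
pairs <- if (length(top) >= 2) utils::combn(top, 2, simplify = FALSE) else list()
tab <- fit_logistic_aic(zs$train, y_train, c(as.list(reps), pairs))
best <- attr(tab, "fits")[[1]]
best_terms <- strsplit(tab$terms[1], " \\+ ")[[1]]
cat(sprintf("\nBest model: %s (AIC %.2f)\n", tab$terms[1], tab$aic[1]))

perf <- rbind(
  evaluate_model(best, zs$train, y_train, "train", 2000, seed + 21),
  evaluate_model(best, zs$test, y_test, "test", 2000, seed + 22),
  evaluate_model(best, zs$original, y_orig, "original", 2000, seed + 23)
)
print(perf, digits = 3)
cv <- cross_validate(zs$train, y_train, best_terms, folds = 10, seed = seed + 24)
cat(sprintf("10-fold CV accuracy: %.3f [%.3f, %.3f]\n",
            cv$accuracy, cv$ci[1], cv$ci[2]))

write.csv(tab, "results/model_aic_table.csv", row.names = FALSE)
write.csv(perf, "results/model_performance.csv", row.names = FALSE)
jsonlite::write_json(
  list(representatives = reps, best_terms = best_terms,
       best_aic = tab$aic[1], cv_accuracy = cv$accuracy, cv_ci = cv$ci),
  "results/selection_summary.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/model_aic_table.csv, results/model_performance.csv, results/selection_summary.json\n")
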